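test_that("empirical Q is flat when outcomes carry no state information", {
  d <- synthetic_design(1500, seed = 41, win_fn = function(d)
    rbinom(nrow(d), 1, 0.6))
  q <- fit_empirical_q(d, n_inducing = 15, n_iters = 300, seed = 2)
  pr <- predict(q, d[1:500, ])
  expect_equal(mean(pr$prob), 0.6, tolerance = 0.05)
  expect_lt(sd(pr$prob), 0.06)
})

make_q_frame <- function(d) d[, c(state_predictors(), "omega", "a", "win")]

test_that("empirical Q learns a constructed state dependence", {
  d <- synthetic_design(2500, seed = 42, win_fn = function(d)
    as.integer(d$puck_y > 0))
  sp <- split_train_test(d, 0.8, seed = 1)
  q <- fit_empirical_q(sp$train, n_inducing = 20, n_iters = 400, seed = 2)
  expect_gte(evaluate_auc(q$svgp, make_q_frame(sp$test), response = "win"), 0.9)
})

test_that("empirical Q separates actions where the action decides the outcome", {
  d <- synthetic_design(2500, seed = 43, a_prob = 0.5, win_fn = function(d)
    as.integer(d$a == 1L))
  q <- fit_empirical_q(d, n_inducing = 20, n_iters = 400, seed = 2)
  probe <- d[1:300, ]
  q1 <- predict(q, probe, a = 1L)$prob
  q0 <- predict(q, probe, a = 0L)$prob
  expect_gt(mean(q1 - q0), 0.5)
})

test_that("final-move EV against a frozen goalie matches the kinematic roll-out", {
  cfg <- game_config(bar_half_height = 0.4)
  trials <- lapply(1:60, function(i) {
    run_trial(synthetic_shooter_policy(shooter_params(skill = 0), 0L, (i - 1) / 59),
              constant_policy(0), cfg, seed = 7000 + i,
              participant_id = "p01", opponent_id = 0L, trial_index = i)
  })
  d <- build_design(trials, standardize = "global")
  ev <- fit_final_move_ev(d, n_inducing = 30, n_iters = 600, seed = 4)
  fm <- ev$final_moves
  pred <- ev_curves(ev, fm)$ev
  agree <- vapply(seq_len(nrow(fm)), function(j) {
    st <- trials[[fm$trial_id[j]]]$states
    i <- which(st$t == fm$t[j])
    dir <- sign(st$puck_u[i + 1])
    if (is.na(dir) || dir == 0) dir <- sign(st$puck_u[i])
    orc <- straight_shot_wins(st$puck_x[i], st$puck_y[i], 0, dir, cfg)
    (pred[j] >= 0.5) == orc
  }, TRUE)
  expect_gte(mean(agree), 0.9)
})

test_that("trials without change points are excluded but outcomes are kept", {
  d <- synthetic_design(600, seed = 44, a_prob = 0.15, win_fn = function(d)
    rbinom(nrow(d), 1, 0.5))
  # erase every change point in trial 1
  d$a[d$trial_id == 1] <- 0L
  expect_message(ev <- fit_final_move_ev(d, n_inducing = 10, n_iters = 150,
                                         seed = 3),
                 "without a change point")
  expect_equal(ev$n_excluded, 1L)
  expect_false(1L %in% ev$final_moves$trial_id)
  # a single-class stratum is an error
  d2 <- d[d$omega == 0, ]
  d2$win <- 1L
  expect_error(fit_final_move_ev(d2, n_inducing = 10, n_iters = 50, seed = 3),
               "single-class")
})

test_that("duplicating the training data barely moves the predictions", {
  ds <- generate_dataset(1, 12, seed = 77)
  d <- build_design(ds)
  X <- as.matrix(d[, c(state_predictors(), "omega")])
  f1 <- fit_svgp(X, d$a, n_inducing = 20, n_iters = 300, seed = 3)
  f2 <- fit_svgp(rbind(X, X), c(d$a, d$a), n_inducing = 20, n_iters = 300,
                 seed = 3)
  expect_lt(mean(abs(predict(f1, X)$prob - predict(f2, X)$prob)), 0.08)
})

test_that("timing analysis produces in-trial optima and unit-consistent deviations", {
  sh <- list(shooter_params(skill = 0.05), shooter_params(skill = 0.95))
  ds <- generate_dataset(2, 20, seed = 91, shooters = sh)
  d <- build_design(ds, standardize = "global")
  ev <- fit_final_move_ev(d, n_inducing = 30, n_iters = 400, seed = 9)
  tm <- timing_analysis(ev, d)
  tt <- tm$trials
  expect_true(all(tt$t_opt >= 1 & tt$t_opt <= tt$n_steps))
  ok <- !is.na(tt$t_move)
  expect_true(all(tt$deviation[ok] >= 0))
  expect_equal(tt$deviation[ok],
               abs(tt$t_move[ok] - tt$t_opt[ok]) / tt$n_steps[ok])
  # reactive timing beats uniform timing
  pp <- aggregate(mean_deviation ~ participant_id, tm$participants, mean)
  expect_lt(pp$mean_deviation[pp$participant_id == "p02"],
            pp$mean_deviation[pp$participant_id == "p01"])
})

test_that("identical participants yield no discriminating statistic", {
  sh <- rep(list(shooter_params(skill = 0.5)), 3)
  ds <- generate_dataset(3, 30, seed = 88, shooters = sh)
  d <- build_design(ds, standardize = "global")
  ev <- fit_final_move_ev(d, n_inducing = 40, n_iters = 500, seed = 9)
  hc <- hypothesis_comparison(timing_analysis(ev, d))
  expect_lt(abs(hc$h1_positioning), 0.08)
  expect_lt(abs(hc$h2_timing), 0.08)
})

test_that("losing straight-line states score below clearly winning ones", {
  cfg <- game_config()
  # too close to the bar to build vertical separation
  expect_false(straight_shot_wins(0.7, 0, 0, 1, cfg))
  # ample room and a head start clear the bar comfortably
  expect_true(straight_shot_wins(-0.5, 0.5, 0, 1, cfg))
  # the same state shooting toward the bar's centre loses
  expect_false(straight_shot_wins(-0.5, 0.5, 0.9, 1, cfg))
  expect_error(straight_shot_wins(0.9, 0, 0, 1, cfg), "past the bar")
})
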