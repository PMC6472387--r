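test_that("goalie tracks the lagged puck position and saturates", {
  cfg <- game_config()
  pol <- goalie_policy(goalie_params(reaction_lag_range = c(0L, 0L)),
                       draws = list(lag = 0L, guess_step = 999L, dir_up = TRUE))
  mem <- pol$init(cfg)
  s <- initial_state(cfg)
  s$puck_y <- 0.5
  out <- pol$step(s, mem)
  expect_gt(out$u, 0) # puck above bar: track upward
  expect_lte(out$u, 1)
  # fixed point: puck at the bar's height, zero lag -> zero input
  s2 <- initial_state(cfg)
  s2$puck_y <- 0.3; s2$bar_y <- 0.3
  out2 <- pol$step(s2, pol$init(cfg))
  expect_equal(out2$u, 0)
})

test_that("guess direction frequency matches the configured probability", {
  cfg <- game_config()
  dirs <- vapply(1:300, function(i) {
    tr <- run_trial(constant_policy(0),
                    goalie_policy(goalie_params(guess_direction_prob = 0.7)),
                    cfg, seed = 4000 + i)
    tr$info$goalie$goalie_guess_dir
  }, 0)
  expect_equal(mean(dirs == 1), 0.7, tolerance = 0.11) # 4 binomial SEs
})

test_that("state-free shooter realises the configured constant switch hazard", {
  cfg <- game_config()
  sp <- shooter_params(base_switch_logit = qnorm(0.05),
                       state_weights = numeric(0), opponent_effect = 0,
                       final_move = "none")
  n_sw <- 0; n_dec <- 0
  for (i in 1:100) {
    tr <- run_trial(synthetic_shooter_policy(sp, 0L, 0), constant_policy(0),
                    cfg, seed = 5000 + i)
    n_sw <- n_sw + length(tr$info$shooter$switch_steps)
    n_dec <- n_dec + length(tr$info$shooter$true_hazard)
  }
  expect_lt(abs(n_sw / n_dec - 0.05), 0.01)
})

test_that("segment-age weighting makes the switch hazard rise within segments", {
  cfg <- game_config()
  sp <- shooter_params(base_switch_logit = -8,
                       state_weights = c(time_since_last_cp = 30),
                       opponent_effect = 0, final_move = "none")
  tr <- run_trial(synthetic_shooter_policy(sp, 0L, 0), constant_policy(0),
                  cfg, seed = 77)
  hz <- tr$info$shooter$true_hazard
  sw <- tr$info$shooter$switch_steps
  bounds <- c(0, sw, length(hz))
  for (k in seq_len(length(bounds) - 1)) {
    seg <- hz[(bounds[k] + 1):bounds[k + 1]]
    if (length(seg) >= 3) expect_true(all(diff(seg) > 0))
  }
})

test_that("a pure opponent shift moves switch rates by the probit closed form", {
  base <- qnorm(0.03); delta <- 0.8
  sp <- shooter_params(base_switch_logit = base, state_weights = numeric(0),
                       opponent_effect = delta, final_move = "none")
  cfg <- game_config()
  rate_for <- function(om) {
    n_sw <- 0; n_dec <- 0
    for (i in 1:80) {
      tr <- run_trial(synthetic_shooter_policy(sp, om, 0), constant_policy(0),
                      cfg, seed = 6000 + i + 500 * om)
      n_sw <- n_sw + length(tr$info$shooter$switch_steps)
      n_dec <- n_dec + length(tr$info$shooter$true_hazard)
    }
    n_sw / n_dec
  }
  expect_lt(abs(rate_for(0L) - 0.03), 0.008)
  expect_lt(abs(rate_for(1L) - pnorm(base + delta)), 0.015)
})

test_that("dataset generation records per-opponent ordinals and round-trips by CSV", {
  ds <- generate_dataset(2, 5, seed = 31)
  expect_length(ds$trials, 20) # 2 participants x 2 opponents x 5 trials
  idx <- vapply(ds$trials, function(t) t$trial_index, 0L)
  om <- vapply(ds$trials, function(t) t$opponent_id, 0L)
  pid <- vapply(ds$trials, function(t) t$participant_id, "")
  for (p in unique(pid)) for (o in 0:1)
    expect_setequal(idx[pid == p & om == o], 1:5)

  path <- tempfile(fileext = ".csv")
  write_trials_csv(ds$trials, path)
  back <- read_trials_csv(path)
  key <- c("participant_id", "opponent_id", "trial_index", "t")
  d1 <- build_design(ds$trials, standardize = "none")
  d2 <- build_design(back, standardize = "none")
  d1 <- d1[do.call(order, d1[key]), setdiff(names(d1), "trial_id")]
  d2 <- d2[do.call(order, d2[key]), setdiff(names(d2), "trial_id")]
  rownames(d1) <- rownames(d2) <- NULL
  expect_equal(d1, d2)
})

test_that("dataset generation is deterministic in the seed", {
  a <- trials_to_df(generate_dataset(1, 4, seed = 13)$trials)
  b <- trials_to_df(generate_dataset(1, 4, seed = 13)$trials)
  c <- trials_to_df(generate_dataset(1, 4, seed = 14)$trials)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("default shooters produce the task's sparse change-point fraction", {
  d <- small_design()
  more <- build_design(generate_dataset(3, 25, seed = 61))
  rate <- mean(c(d$a, more$a))
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("shooter joystick magnitude is maximal except at direction flips", {
  ds <- small_dataset()
  for (tr in ds$trials[1:6]) {
    u <- tr$states$puck_u[-1] # step 0 has no input yet
    expect_true(all(abs(u) == 1))
  }
})
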