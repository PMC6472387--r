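test_that("analytic posterior-mean gradients match central finite differences", {
  fx <- probit1d()
  set.seed(21)
  pts <- matrix(runif(30, -1.8, 1.8), ncol = 1)
  gr <- latent_gradient(fx$fit, pts)
  h <- 1e-4
  fd <- (predict(fx$fit, pts + h)$fmean - predict(fx$fit, pts - h)$fmean) / (2 * h)
  rel <- abs(gr$mean[, 1] - fd) / pmax(abs(gr$mean[, 1]), 1e-8)
  expect_lt(max(rel), 1e-5)
})

test_that("a mirror-symmetric posterior has zero gradient at the symmetry point", {
  kern <- ard_kernel(1.5, 0.8)
  Z <- matrix(c(-1.5, -0.5, 0.5, 1.5), ncol = 1)
  R <- chol(penaltygp:::kernel_gram(Z, kern, 1e-6))
  u_sym <- c(2, 1, 1, 2) # even inducing mean
  obj <- structure(list(kernel = kern, Z = Z,
                        m_v = backsolve(R, u_sym, transpose = TRUE),
                        C = diag(4), R = R, jitter = 1e-6, inputs = "x1",
                        n_train = 0L, elbo_trace = NA_real_,
                        base_rate = NA_real_), class = "svgp")
  gr <- latent_gradient(obj, matrix(0, 1, 1))
  expect_equal(gr$mean[1, 1], 0, tolerance = 1e-10)
})

test_that("gradient covariance reverts to the prior level away from data", {
  fx <- probit1d()
  gr <- latent_gradient(fx$fit, matrix(100, 1, 1))
  prior_var <- fx$fit$kernel$sigma2 / fx$fit$kernel$lambda^2
  expect_equal(gr$cov[1, 1, 1], prior_var, tolerance = 1e-6 * prior_var)
  expect_gt(gr$cov[1, 1, 1], 0)
  expect_error(latent_gradient(list(), matrix(0)), "fitted svgp")
})

test_that("nu is the squared uncertainty-normalised gradient", {
  gr <- structure(list(mean = matrix(c(2, 0), 2, 1),
                       sd = matrix(c(1, 1), 2, 1),
                       cov = array(1, c(1, 1, 2)), inputs = "x1"),
                  class = "gp_gradient")
  expect_equal(sensitivity_index(gr, 1), c(4, 0))
  expect_equal(sensitivity_index(gr, "x1"), c(4, 0))
  gr$sd[1, 1] <- 0
  expect_error(sensitivity_index(gr, 1), "degenerate")
  expect_error(sensitivity_index(gr, "x9"), "unknown")
})

test_that("whitened quadratic form matches its closed forms and the PCA route", {
  expect_equal(whitened_quadform(c(3, 4), diag(2)), 25)
  expect_equal(whitened_quadform(c(2, 1), diag(c(4, 1))), 2)
  set.seed(31)
  for (i in 1:200) {
    A <- matrix(rnorm(4), 2)
    S <- crossprod(A) + diag(0.1, 2)
    g <- rnorm(2)
    expect_equal(whitened_quadform(g, S, "cholesky"),
                 whitened_quadform(g, S, "eigen"), tolerance = 1e-10)
    expect_equal(whitened_quadform(g, S), drop(t(g) %*% solve(S) %*% g),
                 tolerance = 1e-9)
  }
  expect_error(whitened_quadform(c(1, 1), matrix(c(1, 1, 1, 1), 2)),
               "positive definite")
})

test_that("opponent-action sensitivity equals the whitened block form", {
  obj <- prior_svgp(ard_kernel(1.3, c(0.7, 1.2)), inputs = c("bar_y", "bar_vy"))
  X <- matrix(rnorm(10), ncol = 2)
  colnames(X) <- c("bar_y", "bar_vy")
  gr <- latent_gradient(obj, X)
  vs <- opponent_action_sensitivity(gr)
  manual <- vapply(1:5, function(k)
    whitened_quadform(gr$mean[k, ], gr$cov[, , k]), 0)
  expect_equal(vs, manual)
  expect_error(opponent_action_sensitivity(gr, dims = c("a", "b")),
               "two model inputs")
})

test_that("nu under prior draws is chi-squared(1)", {
  obj <- prior_svgp()
  gr0 <- latent_gradient(obj, matrix(c(0.3, -0.2), 1))
  S <- gr0$cov[, , 1]
  set.seed(6)
  draws <- rmvn0(2000, S)
  nu <- (draws[, 1] / sqrt(S[1, 1]))^2
  ks <- suppressWarnings(ks.test(nu, function(q) pchisq(q, df = 1)))
  expect_gt(ks$p.value, 0.01)
})

test_that("noncentral chi-squared intervals achieve nominal coverage", {
  set.seed(7)
  n <- 2000
  mu <- rnorm(n, 0, 1.5)
  sdv <- runif(n, 0.5, 2)
  g <- rnorm(n, mu, sdv)
  nu_true <- (g / sdv)^2
  ci <- sensitivity_interval((mu / sdv)^2, df = 1)
  cov95 <- mean(nu_true >= ci$lo & nu_true <= ci$hi)
  expect_gt(cov95, 0.92)
  expect_lt(cov95, 0.98)
})

test_that("aggregation preserves constants and groups correctly", {
  rec <- data.frame(
    participant_id = rep(c("a", "b"), each = 4),
    trial_id = rep(1:4, each = 2),
    opponent_id = rep(c(0L, 1L, 0L, 1L), each = 2),
    t = rep(1:2, 4),
    nu_x = 2.5, varsigma = 1.25)
  by_tr <- aggregate_sensitivity(rec, "trial")
  expect_true(all(by_tr$nu_x == 2.5))
  expect_equal(nrow(by_tr), 4)
  by_p <- aggregate_sensitivity(rec, "participant")
  expect_true(all(by_p$varsigma == 1.25))
  expect_equal(nrow(by_p), 4) # 2 participants x 2 opponents
  expect_identical(aggregate_sensitivity(rec, "timepoint"), rec)
})

test_that("phase contrast flags late-only opponent sensitivity", {
  grid <- expand.grid(participant_id = "a", trial_id = 1:20, t = 1:40,
                      stringsAsFactors = FALSE)
  grid$opponent_id <- grid$trial_id %% 2L
  # equal sensitivity early; 4x higher against opponent 1 late
  grid$varsigma <- ifelse(grid$t > 20 & grid$opponent_id == 1, 4, 1)
  pc <- opponent_phase_contrast(grid)
  expect_equal(pc$early, 0, tolerance = 1e-12)
  expect_gt(pc$late, 1) # log(4)
})
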