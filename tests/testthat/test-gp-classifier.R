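test_that("ARD-RBF kernel has the decaying closed form and a PSD Gram matrix", {
  k <- ard_kernel(1, 1)
  expect_equal(kernel_eval(0.3, 0.3, k), 1)
  expect_equal(kernel_eval(0, 1, k), exp(-0.5), tolerance = 1e-12)
  k2 <- ard_kernel(2.5, c(0.5, 3))
  expect_equal(kernel_eval(c(0, 0), c(0, 0), k2), 2.5)
  expect_equal(kernel_eval(c(1, 1), c(0, 0), k2),
               2.5 * exp(-(1 / (2 * 0.25) + 1 / (2 * 9))))
  # symmetry and boundedness
  x <- c(0.4, -1); y <- c(-0.2, 0.7)
  expect_equal(kernel_eval(x, y, k2), kernel_eval(y, x, k2))
  expect_lte(kernel_eval(x, y, k2), k2$sigma2)
  # PSD on random points
  set.seed(2)
  P <- matrix(rnorm(10), ncol = 2)
  G <- penaltygp:::kernel_cross(P, P, k2)
  expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  expect_error(ard_kernel(-1, 1), "positive")
  expect_error(ard_kernel(1, c(1, -2)), "positive")
  expect_error(kernel_eval(c(1, 2), 1, k2), "mismatch")
})

test_that("SVGP recovers a known 1-D probit function", {
  fx <- probit1d()
  g <- seq(-1.5, 1.5, length.out = 31)
  p <- predict(fx$fit, matrix(g, ncol = 1))$prob
  expect_lt(max(abs(p - pnorm(1.5 * g))), 0.05)
})

test_that("ELBO improves and ends in a non-decreasing moving average", {
  tr <- probit1d()$fit$elbo_trace
  expect_true(all(is.finite(tr)))
  expect_gt(mean(tail(tr, 100)), mean(head(tr, 100)))
  expect_gt(mean(tail(tr, 100)), mean(tr[401:500]))
})

test_that("flipping every label negates the fitted latent", {
  set.seed(11)
  n <- 1200
  x <- matrix(runif(n, -2, 2), ncol = 1)
  y <- rbinom(n, 1, pnorm(1.2 * x[, 1]))
  f1 <- fit_svgp(x, y, n_inducing = 15, n_iters = 300, seed = 3)
  f2 <- fit_svgp(x, 1L - y, n_inducing = 15, n_iters = 300, seed = 3)
  g <- matrix(seq(-1.5, 1.5, length.out = 21), ncol = 1)
  expect_equal(predict(f2, g)$fmean, -predict(f1, g)$fmean, tolerance = 1e-8)
})

test_that("ARD prunes an irrelevant input dimension", {
  set.seed(12)
  n <- 2500
  X <- cbind(runif(n, -2, 2), runif(n, -2, 2))
  y <- rbinom(n, 1, pnorm(1.5 * X[, 1]))
  fit <- fit_svgp(X, y, n_inducing = 20, n_iters = 600, lr_hyper = 0.1, seed = 4)
  expect_gt(fit$kernel$lambda[2] / fit$kernel$lambda[1], 3)
})

test_that("predictions use the exact probit-Gaussian integral and revert to the prior", {
  fx <- probit1d()
  pr <- predict(fx$fit, matrix(c(-1, 0, 1), ncol = 1))
  expect_true(all(pr$prob > 0 & pr$prob < 1))
  expect_equal(pr$prob, pnorm(pr$fmean / sqrt(1 + pr$fvar)))
  far <- predict(fx$fit, matrix(100, 1, 1))
  expect_equal(far$fmean, 0, tolerance = 1e-8)
  expect_equal(far$fvar, fx$fit$kernel$sigma2, tolerance = 1e-6)
  expect_equal(far$prob, 0.5, tolerance = 1e-8) # zero mean at any variance
  expect_error(predict(fx$fit, matrix(0, 1, 3)), "mismatch")
})

test_that("degenerate training inputs are rejected with clear errors", {
  x <- matrix(rnorm(50), ncol = 1)
  expect_error(fit_svgp(x, rep(1L, 50)), "both classes")
  expect_error(fit_svgp(x, rep(c(0.2, 0.8), 25)), "binary")
  expect_error(fit_svgp(x, rep(0:1, 20)), "sizes differ")
})

test_that("held-out AUC is 1 when separable, near 1/2 under shuffled labels", {
  fx <- probit1d()
  held <- data.frame(x1 = seq(-2, 2, length.out = 400))
  held$a <- as.integer(held$x1 > 0) # separable by the recovered latent
  expect_gte(evaluate_auc(fx$fit, held), 0.99)
  set.seed(9)
  held$a <- sample(held$a)
  expect_lt(abs(evaluate_auc(fx$fit, held) - 0.5), 0.08)
  held$a <- 1L
  expect_error(evaluate_auc(fx$fit, held), "single class")
})

test_that("our variational fit agrees with an independent GP classifier", {
  suppressMessages(library(kernlab))
  set.seed(42)
  n <- 1200
  x <- matrix(runif(n, -2, 2), ncol = 1)
  colnames(x) <- "x1"
  y <- rbinom(n, 1, pnorm(1.2 * x[, 1]))
  fit <- fit_svgp(x, y, n_inducing = 15, n_iters = 400, seed = 3)
  ref <- gausspr(x, factor(y), kernel = "rbfdot")
  g <- matrix(seq(-1.5, 1.5, length.out = 25), ncol = 1)
  colnames(g) <- "x1"
  p1 <- predict(fit, g)$prob
  p2 <- predict(ref, g, type = "probabilities")[, 2]
  expect_gt(cor(p1, p2), 0.97)
  expect_lt(max(abs(p1 - p2)), 0.12)
})

test_that("predicted probabilities are calibrated on ample synthetic data", {
  set.seed(8)
  n <- 20000
  X <- cbind(runif(n, -2, 2), runif(n, -2, 2))
  y <- rbinom(n, 1, pnorm(0.8 * X[, 1] - 1.2 * X[, 1] * X[, 2]))
  fit <- fit_svgp(X, y, n_inducing = 25, n_iters = 300, seed = 2)
  p <- predict(fit, X)$prob
  bins <- cut(p, quantile(p, 0:10 / 10), include.lowest = TRUE)
  obs <- tapply(y, bins, mean)
  pred <- tapply(p, bins, mean)
  slope <- coef(lm(obs ~ pred))[[2]]
  expect_gt(slope, 0.8)
  expect_lt(slope, 1.2)
})

test_that("probit-scale averaging differs from probability averaging as intended", {
  p <- c(0.01, 0.5)
  expect_equal(average_probability(p, "probability"), 0.255)
  expect_equal(average_probability(p, "probit"),
               pnorm(mean(qnorm(p))), tolerance = 1e-12)
  expect_lt(average_probability(p, "probit"),
            average_probability(p, "probability"))
})
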