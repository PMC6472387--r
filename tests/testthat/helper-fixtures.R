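# Shared fixtures, built once per test run and memoised.

fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (!exists(name, envir = fixture_cache)) assign(name, fn(), envir = fixture_cache)
  get(name, envir = fixture_cache)
}

small_dataset <- function() fixture("small_dataset", function() {
  generate_dataset(2, 8, seed = 101)
})

small_design <- function() fixture("small_design", function() {
  build_design(small_dataset())
})

# A well-converged 1-D probit fit with known generating function
# f(x) = 1.5 x, used across the GP and sensitivity tests.
probit1d <- function() fixture("probit1d", function() {
  set.seed(42)
  n <- 4000
  x <- matrix(runif(n, -2, 2), ncol = 1)
  colnames(x) <- "x1"
  y <- rbinom(n, 1, pnorm(1.5 * x[, 1]))
  fit <- fit_svgp(x, y, n_inducing = 30, n_iters = 1000, seed = 3)
  list(x = x, y = y, fit = fit)
})

# An svgp object whose variational posterior equals the prior (whitened mean
# zero, identity Cholesky), so latent_gradient returns prior quantities.
prior_svgp <- function(kern = ard_kernel(1.7, c(0.9, 1.4)),
                       inputs = c("x1", "x2"), seed = 5, m = 12L) {
  d <- length(kern$lambda)
  Z <- withr::with_seed(seed, matrix(rnorm(m * d), ncol = d))
  structure(list(
    kernel = kern, Z = Z, m_v = rep(0, m), C = diag(m),
    R = chol(penaltygp:::kernel_gram(Z, kern, 1e-6)),
    jitter = 1e-6, inputs = inputs, n_train = 0L,
    elbo_trace = NA_real_, base_rate = NA_real_
  ), class = "svgp")
}

# Draw n samples from N(0, S) using base R only.
rmvn0 <- function(n, S) {
  L <- t(chol(S))
  t(L %*% matrix(rnorm(n * nrow(S)), nrow = nrow(S)))
}

# Build a ps_trial directly from a data.frame of states.
manual_trial <- function(states, participant_id = "p", opponent_id = 0L,
                         trial_index = 1L, outcome = "win") {
  structure(list(states = states, participant_id = participant_id,
                 opponent_id = as.integer(opponent_id),
                 trial_index = as.integer(trial_index),
                 outcome = outcome, info = NULL),
            class = "ps_trial")
}

# Synthetic design rows (no simulator) for the value-model unit tests.
synthetic_design <- function(n, seed, win_fn, a_prob = 0.1) {
  withr::with_seed(seed, {
    d <- data.frame(
      puck_x = rnorm(n), puck_y = rnorm(n), bar_y = rnorm(n),
      puck_vy = rnorm(n), bar_vy = rnorm(n),
      time_since_last_cp = runif(n), opponent_experience = runif(n),
      omega = rbinom(n, 1, 0.5)
    )
    d$a <- rbinom(n, 1, a_prob)
    d$win <- win_fn(d)
    d$participant_id <- "p01"
    d$trial_id <- rep(seq_len(ceiling(n / 50)), each = 50)[seq_len(n)]
    d$opponent_id <- d$omega
    d$trial_index <- d$trial_id
    d$t <- stats::ave(seq_len(n), d$trial_id, FUN = seq_along)
    d
  })
}
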