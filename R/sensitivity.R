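#' Posterior gradient of the latent GP
#'
#' Because the latent `f` is a GP with a smooth (ARD-RBF) kernel, its
#' gradient is also a GP. This computes, at each query point, the analytic
#' gradient of the posterior mean and the posterior covariance of the
#' gradient, via the first and second derivatives of the kernel. For the
#' ARD-RBF kernel the prior gradient covariance at a point is diagonal with
#' entries `sigma2 / lambda_i^2`, which the posterior reverts to far from
#' the data.
#'
#' @param object A fitted [fit_svgp()] model.
#' @param Xnew Matrix or data.frame of query points.
#' @return A `gp_gradient` object: `mean` (n x d gradient of the posterior
#'   mean), `sd` (n x d per-dimension posterior standard deviations), `cov`
#'   (d x d x n posterior covariance array), and the input names.
#' @export
latent_gradient <- function(object, Xnew) {
  if (!inherits(object, "svgp")) stop("latent_gradient needs a fitted svgp model")
  Xnew <- select_inputs(object, Xnew)
  Xnew <- as.matrix(Xnew)
  n <- nrow(Xnew); d <- ncol(object$Z)
  if (ncol(Xnew) != d) stop("dimension mismatch")
  kern <- object$kernel
  Knm <- kernel_cross(Xnew, object$Z, kern)
  alpha <- backsolve(object$R, object$m_v) # R^{-1} m_v
  inv_l2 <- 1 / kern$lambda^2
  grad_mean <- matrix(NA_real_, n, d)
  for (i in seq_len(d)) {
    D_i <- outer(-Xnew[, i], object$Z[, i], "+") * inv_l2[i] # (z_i - x_i)/lambda_i^2
    grad_mean[, i] <- (Knm * D_i) %*% alpha
  }
  prior_diag <- kern$sigma2 * inv_l2
  cov_arr <- array(NA_real_, c(d, d, n))
  sd_mat <- matrix(NA_real_, n, d)
  for (k in seq_len(n)) {
    G <- t(Knm[k, ] * sweep(object$Z, 2, Xnew[k, ], "-")) * inv_l2 # d x M
    DB <- t(backsolve(object$R, t(G), transpose = TRUE))
    DBC <- DB %*% object$C
    S <- diag(prior_diag, d) - tcrossprod(DB) + tcrossprod(DBC)
    cov_arr[, , k] <- S
    sd_mat[k, ] <- sqrt(pmax(diag(S), 0))
  }
  structure(list(mean = grad_mean, sd = sd_mat, cov = cov_arr,
                 inputs = object$inputs %||% paste0("x", seq_len(d))),
            class = "gp_gradient")
}

#' Per-input sensitivity index
#'
#' `nu_i(x) = (grad_i f(x) / sigma_i(x))^2`: the squared gradient of the
#' latent posterior mean along input `i`, normalised by the posterior
#' standard deviation of that gradient. Under the null in which the gradient
#' is pure posterior noise, `nu_i` is chi-squared with 1 degree of freedom;
#' normalising downweights highly uncertain gradients.
#'
#' @param grad A [latent_gradient()] result.
#' @param i Input index or name.
#' @return Numeric vector of `nu_i` values (one per query point).
#' @export
sensitivity_index <- function(grad, i) {
  stopifnot(inherits(grad, "gp_gradient"))
  if (is.character(i)) i <- match(i, grad$inputs)
  if (is.na(i) || i < 1 || i > ncol(grad$mean)) stop("unknown input index")
  s <- grad$sd[, i]
  if (any(s <= 0)) stop("degenerate posterior: zero gradient standard deviation")
  (grad$mean[, i] / s)^2
}

#' Whitened squared norm of a gradient block
#'
#' `g' Sigma^{-1} g`, computed either through the Cholesky factor of `Sigma`
#' (solve `L v = g`, return `sum(v^2)`) or through its eigendecomposition
#' (project onto principal components, weight each equally by its standard
#' deviation). The two routes are algebraically identical for any positive
#' definite `Sigma`.
#'
#' @param g Numeric gradient vector.
#' @param Sigma Positive-definite covariance of `g`.
#' @param method `"cholesky"` (default) or `"eigen"`.
#' @return The scalar whitened squared norm.
#' @export
whitened_quadform <- function(g, Sigma, method = c("cholesky", "eigen")) {
  method <- match.arg(method)
  if (method == "cholesky") {
    L <- tryCatch(t(chol(Sigma)), error = function(e)
      stop(sprintf("covariance not positive definite (condition number %.3g)",
                   kappa(Sigma))))
    sum(forwardsolve(L, g)^2)
  } else {
    e <- eigen(Sigma, symmetric = TRUE)
    if (any(e$values <= 0))
      stop(sprintf("covariance not positive definite (condition number %.3g)",
                   kappa(Sigma)))
    sum((crossprod(e$vectors, g))^2 / e$values)
  }
}

#' Opponent-action sensitivity
#'
#' Combines the gradients with respect to the opponent's position and
#' velocity into one index: `varsigma = || L^{-1} grad_xt f ||^2`, where `L`
#' is the Cholesky factor of the posterior covariance of that gradient
#' block. Equivalent to a PCA whitening of the two coordinates with equal
#' weight on each component.
#'
#' @param grad A [latent_gradient()] result.
#' @param dims The two opponent coordinates; defaults to
#'   `c("bar_y", "bar_vy")`.
#' @return Numeric vector of `varsigma` values (one per query point).
#' @export
opponent_action_sensitivity <- function(grad, dims = c("bar_y", "bar_vy")) {
  stopifnot(inherits(grad, "gp_gradient"))
  idx <- if (is.character(dims)) match(dims, grad$inputs) else dims
  if (anyNA(idx) || length(idx) != 2L)
    stop("opponent block must name two model inputs")
  vapply(seq_len(nrow(grad$mean)), function(k) {
    whitened_quadform(grad$mean[k, idx], grad$cov[idx, idx, k])
  }, 0)
}

#' Noncentral chi-squared credible interval for a sensitivity index
#'
#' A sensitivity index built from a Gaussian gradient with posterior mean
#' `m` and standard deviation `s` is distributed as noncentral chi-squared
#' with `df` degrees of freedom and noncentrality `(m/s)^2` (summed over the
#' block); interval endpoints are its quantiles.
#'
#' @param index Observed index values (`nu` with `df = 1`, `varsigma` with
#'   `df = 2`).
#' @param df Degrees of freedom of the index.
#' @param level Coverage level. Default `0.95`.
#' @return A data.frame with `lo` and `hi`.
#' @export
sensitivity_interval <- function(index, df = 1, level = 0.95) {
  a <- (1 - level) / 2
  data.frame(lo = qchisq(a, df = df, ncp = index),
             hi = qchisq(1 - a, df = df, ncp = index))
}

#' Per-timepoint sensitivity records for a design
#'
#' Evaluates the latent gradient at every design row and assembles the eight
#' per-input indices (`nu_` columns, seven state predictors plus opponent
#' identity), the combined opponent-action sensitivity `varsigma`, and 95%
#' noncentral chi-squared intervals for `varsigma`.
#'
#' @param object A fitted policy `svgp`.
#' @param design A [build_design()] data.frame (standardised like the
#'   training data).
#' @param level Credible level for the intervals.
#' @return A data.frame keyed by `participant_id`, `trial_id`, `opponent_id`,
#'   and `t`, with one `nu_*` column per model input, `varsigma`, and
#'   `varsigma_lo`/`varsigma_hi`.
#' @export
sensitivity_records <- function(object, design, level = 0.95) {
  grad <- latent_gradient(object, design)
  nu <- vapply(seq_along(grad$inputs), function(i) sensitivity_index(grad, i),
               numeric(nrow(design)))
  colnames(nu) <- paste0("nu_", grad$inputs)
  vs <- opponent_action_sensitivity(grad)
  ci <- sensitivity_interval(vs, df = 2, level = level)
  out <- data.frame(
    participant_id = design$participant_id,
    trial_id = design$trial_id,
    opponent_id = design$opponent_id,
    t = design$t,
    nu, varsigma = vs, varsigma_lo = ci$lo, varsigma_hi = ci$hi,
    stringsAsFactors = FALSE
  )
  out
}

#' Aggregate sensitivity records across levels of granularity
#'
#' @param records A [sensitivity_records()] data.frame.
#' @param level `"timepoint"` (identity), `"trial"`, or `"participant"`.
#' @return A data.frame of group means of every index column.
#' @export
aggregate_sensitivity <- function(records, level = c("timepoint", "trial",
                                                     "participant")) {
  level <- match.arg(level)
  if (level == "timepoint") return(records)
  dt <- data.table::as.data.table(records)
  cols <- setdiff(names(records),
                  c("participant_id", "trial_id", "opponent_id", "t"))
  by <- switch(level,
               trial = c("participant_id", "opponent_id", "trial_id"),
               participant = c("participant_id", "opponent_id"))
  if (nrow(dt) == 0L) stop("no records to aggregate")
  as.data.frame(dt[, lapply(.SD, mean), by = by, .SDcols = cols])
}

#' Early/late opponent-sensitivity contrast per participant
#'
#' For each participant and trial phase (early = first half of the trial's
#' steps, late = second half; configurable), the difference in mean log
#' opponent-action sensitivity between the two opponent conditions
#' (`omega = 1` minus `omega = 0`). Positive values mean higher sensitivity
#' to the human-like opponent in that phase.
#'
#' @param records A [sensitivity_records()] data.frame.
#' @param split Fraction of the trial separating early from late. Default `0.5`.
#' @return A data.frame with `participant_id`, `early`, `late`, and
#'   `consistent` (same sign in both phases).
#' @export
opponent_phase_contrast <- function(records, split = 0.5) {
  dt <- data.table::as.data.table(records)
  dt[, phase := ifelse(t <= split * max(t), "early", "late"),
     by = c("participant_id", "trial_id")]
  agg <- dt[, .(mlog = mean(log(pmax(varsigma, 1e-12)))),
            by = c("participant_id", "phase", "opponent_id")]
  out <- lapply(split(agg, agg$participant_id), function(d) {
    gv <- function(ph) {
      x <- d[d$phase == ph, ]
      if (nrow(x) < 2L) return(NA_real_)
      x$mlog[x$opponent_id == 1] - x$mlog[x$opponent_id == 0]
    }
    data.frame(participant_id = d$participant_id[1],
               early = gv("early"), late = gv("late"))
  })
  out <- do.call(rbind, out)
  out$consistent <- sign(out$early) == sign(out$late)
  rownames(out) <- NULL
  out
}
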