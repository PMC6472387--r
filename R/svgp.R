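#' Sparse variational Gaussian-process probit classification
#'
#' Binary GP classification with a probit link and an ARD-RBF kernel,
#' fitted by sparse variational inference: the posterior over the latent
#' function `f` (with `P(y = 1 | f) = pnorm(f)`) is summarised at `M`
#' inducing points, whose k-means-initialised locations are held fixed while
#' the whitened variational distribution and the kernel hyperparameters are
#' learned jointly by stochastic gradient ascent (Adam) on the evidence lower
#' bound (ELBO) — an empirical Bayes treatment of the hyperparameters. The
#' expected log-likelihood is computed by Gauss-Hermite quadrature; gradients
#' with respect to the variational parameters are analytic, and the few
#' kernel hyperparameters are refreshed by central finite differences of the
#' ELBO every `hyper_every` iterations.
#'
#' @param X Numeric matrix or data.frame of inputs (rows = observations).
#' @param y Binary labels (0/1 or logical); both classes must be present.
#' @param n_inducing Number of inducing points `M` (capped at `nrow(X)`).
#' @param n_iters Number of full-batch (or minibatch) Adam iterations.
#' @param lr Adam learning rate for the variational parameters.
#' @param lr_hyper Adam learning rate for kernel hyperparameters.
#' @param hyper_every Refresh hyperparameter gradients every this many
#'   iterations (finite differences are the costly part of an iteration).
#' @param batch_size Optional minibatch size; `NULL` (default) uses the full
#'   data each iteration with no gradient noise.
#' @param jitter Diagonal jitter added to the inducing Gram matrix, as a
#'   fraction of the kernel variance. Default `1e-6`.
#' @param quad_points Gauss-Hermite nodes for the likelihood integral.
#' @param seed Integer seed covering initialisation and any minibatching.
#' @param verbose Print ELBO progress.
#' @return An object of class `svgp`: kernel hyperparameters (`kernel`),
#'   inducing inputs `Z`, whitened variational mean and Cholesky factor
#'   (`m_v`, `C`), the Cholesky factor `R` of the inducing Gram matrix,
#'   input column names, and the per-iteration `elbo_trace`.
#' @seealso [predict.svgp()], [evaluate_auc()], [latent_gradient()]
#' @export
fit_svgp <- function(X, y, n_inducing = 50L, n_iters = 1000L,
                     lr = 0.05, lr_hyper = 0.05, hyper_every = 10L,
                     batch_size = NULL, jitter = 1e-6, quad_points = 20L,
                     seed = 1L, verbose = FALSE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.logical(y)) y <- as.integer(y)
  if (!is.numeric(y) || !all(y %in% c(0, 1)))
    stop("labels must be binary (0/1)")
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("both classes must be present in the training labels")
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  n <- nrow(X); d <- ncol(X)
  M <- min(as.integer(n_inducing), n)
  gh <- pracma::gaussHermite(as.integer(quad_points))
  gw <- gh$w / sqrt(pi)
  gx <- sqrt(2) * gh$x

  withr::with_seed(as.integer(seed), {
    Z <- init_inducing(X, M)
    lsig <- 0 # log sigma^2
    llam <- log(pmax(apply(X, 2, sd), 0.05))
    m_v <- numeric(M)
    C <- diag(0.5, M)

    tsgn <- 2 * y - 1

    # ELBO and analytic variational gradients at the current kernel
    eval_state <- function(lsig, llam, idx) {
      kern <- ard_kernel(exp(lsig), exp(llam))
      R <- chol(kernel_gram(Z, kern, jitter))
      Knm <- kernel_cross(X[idx, , drop = FALSE], Z, kern)
      B <- t(backsolve(R, t(Knm), transpose = TRUE))
      list(kern = kern, R = R, B = B, idx = idx)
    }
    elbo_terms <- function(st, m_v, C, want_grad = TRUE) {
      B <- st$B
      nb <- nrow(B)
      scale <- n / nb
      mu <- drop(B %*% m_v)
      BC <- B %*% C
      s2 <- pmax(st$kern$sigma2 - rowSums(B^2) + rowSums(BC^2), 1e-12)
      s <- sqrt(s2)
      tb <- tsgn[st$idx]
      arg <- tb * (outer(mu, rep(1, length(gx))) + s %o% gx)
      logPhi <- pnorm(arg, log.p = TRUE)
      ll <- drop(logPhi %*% gw)
      kl <- 0.5 * (sum(C^2) + sum(m_v^2) - M) - sum(log(diag(C)))
      elbo <- scale * sum(ll) - kl
      if (!want_grad) return(list(elbo = elbo))
      r <- exp(dnorm(arg, log = TRUE) - logPhi)
      gmu <- tb * drop(r %*% gw)
      gs <- tb * drop(r %*% (gw * gx))
      gs2 <- gs / (2 * s)
      g_mv <- scale * drop(crossprod(B, gmu)) - m_v
      G_C <- 2 * scale * crossprod(B, gs2 * BC) - C + diag(1 / diag(C), M)
      G_C[upper.tri(G_C)] <- 0
      list(elbo = elbo, g_mv = g_mv, G_C = G_C)
    }

    # Adam state: variational block and hyperparameter block
    adam_new <- function(len) list(m = numeric(len), v = numeric(len), t = 0L)
    adam_step <- function(stt, g, rate) {
      stt$t <- stt$t + 1L
      stt$m <- 0.9 * stt$m + 0.1 * g
      stt$v <- 0.999 * stt$v + 0.001 * g^2
      mhat <- stt$m / (1 - 0.9^stt$t)
      vhat <- stt$v / (1 - 0.999^stt$t)
      stt$delta <- rate * mhat / (sqrt(vhat) + 1e-8)
      stt
    }
    n_var <- M + M * (M + 1L) / 2L
    ad_var <- adam_new(n_var)
    ad_hyp <- adam_new(1L + d)
    low_idx <- which(lower.tri(matrix(0, M, M), diag = TRUE))
    pack_C <- function(C) {
      Cm <- C; diag(Cm) <- log(diag(C)); Cm[low_idx]
    }
    unpack_C <- function(v) {
      C <- matrix(0, M, M); C[low_idx] <- v; diag(C) <- exp(diag(C)); C
    }
    grad_C_raw <- function(G_C, C) {
      G <- G_C; diag(G) <- diag(G_C) * diag(C); G[low_idx]
    }

    elbo_trace <- numeric(n_iters)
    h <- 1e-3
    g_hyp <- numeric(1L + d)
    for (it in seq_len(n_iters)) {
      idx <- if (is.null(batch_size) || batch_size >= n) seq_len(n)
             else sample.int(n, batch_size)
      st <- eval_state(lsig, llam, idx)
      res <- elbo_terms(st, m_v, C)
      if (!is.finite(res$elbo))
        stop(sprintf(paste0("ELBO diverged (non-finite) at iteration %d; ",
                            "log sigma2 = %.3f, log lambda in [%.3f, %.3f]"),
                     it, lsig, min(llam), max(llam)))
      elbo_trace[it] <- res$elbo

      g_var <- c(res$g_mv, grad_C_raw(res$G_C, C))
      ad_var <- adam_step(ad_var, g_var, lr)
      m_v <- m_v + ad_var$delta[seq_len(M)]
      Cv <- pack_C(C) + ad_var$delta[-seq_len(M)]
      C <- unpack_C(Cv)

      if (it %% hyper_every == 0L || it == 1L) {
        hyp <- c(lsig, llam)
        for (j in seq_along(hyp)) {
          hp <- hyp; hp[j] <- hp[j] + h
          hm <- hyp; hm[j] <- hm[j] - h
          ep <- elbo_terms(eval_state(hp[1], hp[-1], idx), m_v, C,
                           want_grad = FALSE)$elbo
          em <- elbo_terms(eval_state(hm[1], hm[-1], idx), m_v, C,
                           want_grad = FALSE)$elbo
          g_hyp[j] <- (ep - em) / (2 * h)
        }
        ad_hyp <- adam_step(ad_hyp, g_hyp, lr_hyper)
        lsig <- lsig + ad_hyp$delta[1]
        llam <- llam + ad_hyp$delta[-1]
        llam <- clamp(llam, -6, 8) # keep length scales numerically sane
        lsig <- clamp(lsig, -6, 6)
      }
      if (verbose && (it %% 100L == 0L || it == 1L))
        message(sprintf("iter %5d  elbo %.2f", it, res$elbo))
    }

    kern <- ard_kernel(exp(lsig), exp(llam))
    R <- chol(kernel_gram(Z, kern, jitter))
    structure(list(
      kernel = kern, Z = Z, m_v = m_v, C = C, R = R,
      jitter = jitter, inputs = colnames(X),
      elbo_trace = elbo_trace, n_train = n,
      base_rate = mean(y)
    ), class = "svgp")
  })
}

init_inducing <- function(X, M) {
  if (M >= nrow(unique(X))) {
    Z <- unique(X)[seq_len(min(M, nrow(unique(X)))), , drop = FALSE]
    return(Z)
  }
  km <- tryCatch(
    kmeans(X, centers = M, iter.max = 30L, nstart = 1L),
    error = function(e) NULL
  )
  if (!is.null(km)) return(km$centers)
  X[sample.int(nrow(X), M), , drop = FALSE] +
    matrix(rnorm(M * ncol(X), sd = 1e-3), M)
}

svgp_project <- function(object, Xnew) {
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) != ncol(object$Z))
    stop("dimension mismatch: model expects ", ncol(object$Z), " inputs")
  Knm <- kernel_cross(Xnew, object$Z, object$kernel)
  B <- t(backsolve(object$R, t(Knm), transpose = TRUE))
  mu <- drop(B %*% object$m_v)
  BC <- B %*% object$C
  s2 <- pmax(object$kernel$sigma2 - rowSums(B^2) + rowSums(BC^2), 1e-12)
  list(mu = mu, s2 = s2, B = B)
}

select_inputs <- function(object, newdata) {
  if (is.data.frame(newdata)) {
    if (!is.null(object$inputs) && all(object$inputs %in% names(newdata)))
      newdata <- newdata[, object$inputs, drop = FALSE]
    newdata <- as.matrix(newdata)
  }
  newdata
}

#' Predict from a fitted SVGP classifier
#'
#' The class probability is the exact probit-Gaussian integral
#' `pnorm(mu / sqrt(1 + s2))` of `pnorm(f)` under the latent posterior
#' `f ~ N(mu, s2)`; in particular a latent mean of zero gives probability
#' 0.5 at any latent variance.
#'
#' @param object A fitted [fit_svgp()] model.
#' @param newdata Matrix or data.frame of inputs (data.frames are matched on
#'   the training column names).
#' @param ... Unused.
#' @return A data.frame with `prob`, `fmean`, and `fvar`.
#' @export
predict.svgp <- function(object, newdata, ...) {
  pr <- svgp_project(object, select_inputs(object, newdata))
  data.frame(prob = pnorm(pr$mu / sqrt(1 + pr$s2)),
             fmean = pr$mu, fvar = pr$s2)
}

#' @export
print.svgp <- function(x, ...) {
  cat(sprintf("SVGP probit classifier: %d inducing points, %d inputs, %d training rows\n",
              nrow(x$Z), ncol(x$Z), x$n_train))
  cat(sprintf("  kernel variance %.3f; length scales:\n", x$kernel$sigma2))
  nm <- x$inputs %||% paste0("x", seq_along(x$kernel$lambda))
  print(round(setNames(x$kernel$lambda, nm), 3))
  cat(sprintf("  final ELBO %.2f\n", tail(x$elbo_trace, 1)))
  invisible(x)
}

#' Held-out AUC of a fitted classifier
#'
#' Area under the ROC curve on held-out rows, with tied scores handled by
#' rank averaging (Mann-Whitney convention, via pROC).
#'
#' @param object A fitted `svgp`.
#' @param held_out Data.frame of held-out rows containing the model inputs
#'   and the label column.
#' @param response Name of the binary label column. Default `"a"`.
#' @return AUC as a single number in `[0, 1]`.
#' @export
evaluate_auc <- function(object, held_out, response = "a") {
  labels <- held_out[[response]]
  if (length(unique(labels)) < 2L)
    stop("held-out set contains a single class; AUC undefined")
  p <- predict(object, held_out)$prob
  as.numeric(pROC::auc(pROC::roc(labels, p, quiet = TRUE, direction = "<",
                                 levels = c(0, 1))))
}

#' Average probabilities on the probit scale
#'
#' Averaging in normal quantiles (`pnorm(mean(qnorm(p)))`) differs from the
#' plain arithmetic mean of probabilities; summary curves of low-probability
#' events are usually displayed on the probit scale.
#'
#' @param p Probabilities in (0, 1).
#' @param scale `"probit"` (default) or `"probability"`.
#' @return The scalar average on the requested scale.
#' @export
average_probability <- function(p, scale = c("probit", "probability")) {
  scale <- match.arg(scale)
  p <- clamp(p, 1e-12, 1 - 1e-12)
  if (scale == "probit") pnorm(mean(qnorm(p))) else mean(p)
}
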