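#' ARD radial basis function kernel
#'
#' `k(x, x') = sigma2 * exp(-sum_i (x_i - x_i')^2 / (2 * lambda_i^2))`,
#' with one length scale per input dimension (automatic relevance
#' determination): a large `lambda_i` means input `i` barely influences the
#' latent function.
#'
#' @param sigma2 Kernel variance, `> 0`.
#' @param lambda Positive length scales, one per input dimension.
#' @return An `ard_kernel` object.
#' @export
ard_kernel <- function(sigma2 = 1, lambda) {
  if (!is.numeric(sigma2) || length(sigma2) != 1L || sigma2 <= 0)
    stop("sigma2 must be a positive scalar")
  if (!is.numeric(lambda) || any(lambda <= 0))
    stop("all length scales must be positive")
  structure(list(sigma2 = sigma2, lambda = as.numeric(lambda)),
            class = "ard_kernel")
}

#' Evaluate the kernel between two single points
#'
#' @param x,xp Numeric vectors of equal length.
#' @param kernel An [ard_kernel()].
#' @return The scalar covariance value.
#' @export
kernel_eval <- function(x, xp, kernel) {
  stopifnot(inherits(kernel, "ard_kernel"))
  if (length(x) != length(xp) || length(x) != length(kernel$lambda))
    stop("dimension mismatch between points and kernel length scales")
  kernel$sigma2 * exp(-sum((x - xp)^2 / (2 * kernel$lambda^2)))
}

# Cross-covariance matrix between row sets X (n x d) and Z (m x d).
kernel_cross <- function(X, Z, kernel) {
  Xs <- sweep(X, 2, kernel$lambda, "/")
  Zs <- sweep(Z, 2, kernel$lambda, "/")
  d2 <- outer(rowSums(Xs^2), rowSums(Zs^2), "+") - 2 * tcrossprod(Xs, Zs)
  kernel$sigma2 * exp(-0.5 * pmax(d2, 0))
}

# Gram matrix with jitter on the diagonal.
kernel_gram <- function(Z, kernel, jitter = 1e-6) {
  K <- kernel_cross(Z, Z, kernel)
  K + diag(jitter * kernel$sigma2, nrow(Z))
}
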