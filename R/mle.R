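#' Maximum-likelihood Box-Cox exponent for one column
#'
#' Maximizes the classical profile log-likelihood
#' \deqn{LL(\lambda) = -\frac{n}{2}\ln \hat\sigma^2_\lambda +
#'   (\lambda - 1)\sum_i \ln y_i}
#' where \eqn{\hat\sigma^2_\lambda} is the population variance of the
#' transformed data.  This is the Gaussianity-oriented baseline choice of
#' exponent.  A 201-point scan of the search interval guards against local
#' optima before a 1-D numeric refinement.
#'
#' @param y strictly positive numeric vector, length >= 3, non-constant.
#' @param interval search interval for \eqn{\lambda} (default \code{c(-5, 5)}).
#' @return the maximizing exponent (scalar).
#' @export
mle_lambda <- function(y, interval = c(-5, 5)) {
  stopifnot(is.numeric(y), length(y) >= 3L)
  if (any(y <= 0)) stop("Box-Cox MLE requires strictly positive data")
  if (max(y) == min(y)) stop("cannot estimate lambda for a constant vector")
  sumlog <- sum(log(y))
  n <- length(y)
  ll <- function(lam) {
    z <- boxcox_vector(y, lam)
    v <- mean((z - mean(z))^2)
    if (v <= 0) return(-Inf)
    -n / 2 * log(v) + (lam - 1) * sumlog
  }
  grid <- seq(interval[1L], interval[2L], length.out = 201L)
  vals <- vapply(grid, ll, numeric(1L))
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  stats::optimize(ll, lower = lo, upper = hi, maximum = TRUE,
                  tol = 1e-6)$maximum
}
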