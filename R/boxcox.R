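#' Box-Cox power transformation of a positive vector
#'
#' Applies the one-parameter Box-Cox transform element-wise:
#' \deqn{y^{(\lambda)} = (y^\lambda - 1)/\lambda} for \eqn{\lambda \neq 0}
#' and \eqn{\ln(y)} for \eqn{\lambda = 0}.  The transform is monotonic, so
#' it never changes the ordering of the data; at \eqn{\lambda = 1} it reduces
#' to a shift by \eqn{-1}.
#'
#' @param y numeric vector of strictly positive values.
#' @param lambda single finite exponent.  Values with
#'   \code{abs(lambda) < 1e-12} use the logarithmic branch.
#' @return numeric vector of the same length as \code{y}.
#' @examples
#' boxcox_vector(c(1, 1.5, 2), 1)   # shift by -1
#' boxcox_vector(exp(1), 0)         # 1
#' @export
boxcox_vector <- function(y, lambda) {
  stopifnot(is.numeric(y), is.numeric(lambda), length(lambda) == 1L)
  if (!is.finite(lambda)) stop("'lambda' must be finite")
  bad <- which(y <= 0)
  if (length(bad) > 0L) {
    stop(sprintf(
      "Box-Cox transform requires strictly positive data; first offending index: %d (value %g)",
      bad[1L], y[bad[1L]]
    ))
  }
  if (abs(lambda) < .bcx_zero_tol) log(y) else (y^lambda - 1) / lambda
}

# tolerance below which lambda is treated as exactly zero
.bcx_zero_tol <- 1e-12

#' Column-wise Box-Cox transformation of a matrix
#'
#' Applies \code{boxcox_vector} to each column \code{j} of \code{X} with its
#' own exponent \code{lambda[j]}, realizing the multivariate transform
#' parameterized by the vector \eqn{\Lambda = [\lambda_1, \dots, \lambda_p]}.
#'
#' @param X numeric matrix with strictly positive entries,
#'   n samples x p features.
#' @param lambda numeric vector of length \code{ncol(X)}.
#' @return transformed matrix of the same dimensions.
#' @export
boxcox_matrix <- function(X, lambda) {
  X <- as.matrix(X)
  if (length(lambda) != ncol(X)) {
    stop(sprintf("length(lambda) = %d but ncol(X) = %d", length(lambda), ncol(X)))
  }
  out <- X
  for (j in seq_len(ncol(X))) {
    out[, j] <- boxcox_vector(X[, j], lambda[j])
  }
  out
}
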