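#' Fit a min-max scaler into the range [1, 2]
#'
#' Records per-column training minimum and maximum; \code{minmax_apply}
#' then maps each column affinely so the training minimum goes to 1 and the
#' training maximum to 2.  The lower bound guarantees positivity for the
#' Box-Cox step; the upper bound keeps features from exploding under large
#' exponents.  Constant columns map to the range midpoint 1.5.
#'
#' @param X numeric matrix (>= 1 row).
#' @return an object of class \code{"bcx_minmax"} holding the fitted
#'   per-column ranges.
#' @export
minmax_fit <- function(X) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 1L)
  structure(
    list(min = apply(X, 2L, min), max = apply(X, 2L, max)),
    class = "bcx_minmax"
  )
}

#' Apply a fitted min-max scaler
#'
#' Unseen data is extrapolated with the training affine map, then floored at
#' \code{1e-6} so downstream Box-Cox transforms stay defined even when test
#' values fall below the training minimum.
#'
#' @param state a fitted \code{"bcx_minmax"} object.
#' @param X numeric matrix with the same number of columns as the training
#'   data.
#' @return rescaled matrix.
#' @export
minmax_apply <- function(state, X) {
  if (!inherits(state, "bcx_minmax")) {
    stop("'state' is not a fitted min-max scaler; call minmax_fit() first")
  }
  X <- as.matrix(X)
  if (ncol(X) != length(state$min)) {
    stop(sprintf("scaler was fitted on %d columns, data has %d",
                 length(state$min), ncol(X)))
  }
  rng <- state$max - state$min
  out <- X
  for (j in seq_len(ncol(X))) {
    out[, j] <- if (rng[j] > 0) {
      1 + (X[, j] - state$min[j]) / rng[j]
    } else {
      rep(1.5, nrow(X))  # constant training column: range midpoint
    }
  }
  pmax(out, 1e-6)
}

#' Fit a standard (z-score) scaler
#'
#' Records per-column training mean and standard deviation (population
#' convention, divisor n).  Zero-variance columns are centered only
#' (scale fixed at 1).
#'
#' @param X numeric matrix (>= 1 row).
#' @return an object of class \code{"bcx_standard"}.
#' @export
standard_fit <- function(X) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 1L)
  mu <- colMeans(X)
  sdev <- sqrt(colMeans(sweep(X, 2L, mu)^2))
  sdev[sdev == 0] <- 1
  structure(list(mean = mu, sd = sdev), class = "bcx_standard")
}

#' Apply a fitted standard scaler
#'
#' @param state a fitted \code{"bcx_standard"} object.
#' @param X numeric matrix with matching column count.
#' @return standardized matrix.
#' @export
standard_apply <- function(state, X) {
  if (!inherits(state, "bcx_standard")) {
    stop("'state' is not a fitted standard scaler; call standard_fit() first")
  }
  X <- as.matrix(X)
  if (ncol(X) != length(state$mean)) {
    stop(sprintf("scaler was fitted on %d columns, data has %d",
                 length(state$mean), ncol(X)))
  }
  sweep(sweep(X, 2L, state$mean), 2L, state$sd, "/")
}
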