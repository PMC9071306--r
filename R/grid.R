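#' Candidate grid for one-dimensional exponent searches
#'
#' By default 11 evenly spaced values on \eqn{[-5, 5]} (spacing 1).  In
#' \code{"global"} mode candidates are absolute exponent values; after
#' refinement (\code{\link{refine_grid}}) the grid switches to
#' \code{"local"} mode and candidates act as offsets attached to the
#' incumbent coordinate.
#'
#' @param gridsize number of candidates (used when \code{candidates} is not
#'   given).
#' @param candidates strictly increasing numeric vector of candidate values.
#' @param finer_factor grid-scaling factor in (0, 1) used by refinement.
#' @param mode \code{"global"} or \code{"local"}.
#' @return an object of class \code{"bcx_grid"}.
#' @export
grid_spec <- function(gridsize = 11L,
                      candidates = seq(-5, 5, length.out = gridsize),
                      finer_factor = 0.5, mode = c("global", "local")) {
  mode <- match.arg(mode)
  if (any(diff(candidates) <= 0)) stop("'candidates' must be strictly increasing")
  if (finer_factor <= 0 || finer_factor >= 1) {
    stop("'finer_factor' must lie in (0, 1)")
  }
  structure(
    list(candidates = as.numeric(candidates), finer_factor = finer_factor,
         mode = mode, domain = range(candidates)),
    class = "bcx_grid"
  )
}

#' Refine a candidate grid
#'
#' Scales every candidate by \code{finer_factor} (cardinality unchanged) and
#' switches the grid to local mode, so subsequent scans attach the denser
#' candidates as offsets to the incumbent coordinate.
#'
#' @param grid a \code{"bcx_grid"}.
#' @return the refined \code{"bcx_grid"}.
#' @export
refine_grid <- function(grid) {
  stopifnot(inherits(grid, "bcx_grid"))
  grid$candidates <- grid$candidates * grid$finer_factor
  grid$mode <- "local"
  grid
}
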