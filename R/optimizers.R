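#' Configuration for the iterative coordinate grid search
#'
#' The criterion minimized by every search is \eqn{L = 1 - ACC}, i.e. the
#' searches maximize in-sample training accuracy of the wrapped classifier.
#' The three refinement mechanisms trigger on epochs divisible by their
#' respective period: \code{shift_epoch} draws a fresh start point,
#' \code{shuffle_epoch} permutes the direction order, \code{finer_epoch}
#' scales the grid by its \code{finer_factor} and attaches it locally.
#' Each mechanism can be switched off; \code{\link{resolve_preset}} returns
#' the named benchmark settings with only the mechanisms each preset
#' exercises enabled.
#'
#' @param epochs number of full coordinate sweeps.
#' @param shift_epoch period (in epochs) for restarting from a new point.
#' @param shuffle_epoch period for permuting the optimization order.
#' @param finer_epoch period for grid refinement.
#' @param gridsize number of candidates per 1-D scan.
#' @param start_policy initial-point rule: \code{"mle"} (column-wise
#'   maximum-likelihood exponents), \code{"ones"}, or \code{"random"}.
#' @param seed integer seed for shuffles and random start points.
#' @param use_shift,use_shuffle,use_finer logical switches for the three
#'   refinement mechanisms.
#' @return an object of class \code{"bcx_config"}.
#' @export
optimizer_config <- function(epochs = 4L, shift_epoch = 4L,
                             shuffle_epoch = 4L, finer_epoch = 4L,
                             gridsize = 11L,
                             start_policy = c("mle", "ones", "random"),
                             seed = 42L,
                             use_shift = TRUE, use_shuffle = TRUE,
                             use_finer = TRUE) {
  start_policy <- match.arg(start_policy)
  for (v in c(epochs, shift_epoch, shuffle_epoch, finer_epoch, gridsize)) {
    if (!is.numeric(v) || length(v) != 1L || v < 1) {
      stop("epochs, *_epoch and gridsize must be positive integers")
    }
  }
  structure(
    list(epochs = as.integer(epochs), shift_epoch = as.integer(shift_epoch),
         shuffle_epoch = as.integer(shuffle_epoch),
         finer_epoch = as.integer(finer_epoch),
         gridsize = as.integer(gridsize), start_policy = start_policy,
         seed = as.integer(seed), use_shift = isTRUE(use_shift),
         use_shuffle = isTRUE(use_shuffle), use_finer = isTRUE(use_finer)),
    class = "bcx_config"
  )
}

#' In-sample accuracy criterion for exponent selection
#'
#' Applies the Box-Cox transform with the proposed exponent vector, fits and
#' applies a standard scaler, trains the classifier, predicts on the
#' \emph{same} data, and returns the training accuracy.  All grid searches
#' in this package maximize this quantity (equivalently minimize
#' \eqn{1 - ACC}).  The caller is expected to pass data already range
#' standardized to \eqn{[1, 2]}.
#'
#' @param X strictly positive feature matrix (range standardized).
#' @param Y class labels.
#' @param lambda exponent vector, length \code{ncol(X)}.
#' @param spec a \code{"bcx_spec"} classifier specification.
#' @return accuracy in \eqn{[0, 1]}.
#' @export
criterion_accuracy <- function(X, Y, lambda, spec) {
  Xb <- boxcox_matrix(X, lambda)
  Xs <- standard_apply(standard_fit(Xb), Xb)
  clf <- train_classifier(make_classifier(spec), Xs, Y)
  mean(predict_classifier(clf, Xs) == as.character(Y))
}

#' Exhaustive two-dimensional grid search for the exponent pair
#'
#' Evaluates the in-sample criterion at every pair of grid candidates
#' (ascending \eqn{\lambda_1} outer, ascending \eqn{\lambda_2} inner) and
#' keeps the first strict maximizer.
#'
#' @inheritParams criterion_accuracy
#' @param grid a \code{"bcx_grid"}.
#' @param criterion criterion function with the signature of
#'   \code{\link{criterion_accuracy}} (injectable for testing).
#' @return the winning exponent vector (length 2).
#' @export
grid_search_2d <- function(X, Y, spec, grid = grid_spec(),
                           criterion = criterion_accuracy) {
  X <- as.matrix(X)
  if (ncol(X) != 2L) stop("grid_search_2d requires exactly 2 features")
  best_a <- 0
  best <- c(grid$candidates[1L], grid$candidates[1L])
  for (l1 in grid$candidates) {
    for (l2 in grid$candidates) {
      a <- criterion(X, Y, c(l1, l2), spec)
      if (a > best_a) {
        best_a <- a
        best <- c(l1, l2)
      }
    }
  }
  best
}

#' Spherical grid search: one shared exponent for all columns
#'
#' Scans the scalar candidates and returns the winner replicated across all
#' \code{p} coordinates (first strict maximizer on ties).
#'
#' @inheritParams grid_search_2d
#' @return exponent vector of length \code{ncol(X)}.
#' @export
spherical_search <- function(X, Y, spec, grid = grid_spec(),
                             criterion = criterion_accuracy) {
  X <- as.matrix(X)
  p <- ncol(X)
  best_a <- 0
  best <- grid$candidates[1L]
  for (lam in grid$candidates) {
    a <- criterion(X, Y, rep(lam, p), spec)
    if (a > best_a) {
      best_a <- a
      best <- lam
    }
  }
  rep(best, p)
}

#' Diagonal grid search: per-column exponents optimized independently
#'
#' For each direction, all other coordinates are fixed at 1 (the neutral
#' shift-only exponent) and the candidate maximizing the criterion is
#' selected; the per-direction winners are then assembled into the returned
#' vector.  Because each direction is optimized in isolation, the joint
#' accuracy of the assembled vector is \emph{not} guaranteed to reach --- or
#' even match --- the untransformed baseline.
#'
#' @inheritParams grid_search_2d
#' @return exponent vector of length \code{ncol(X)}.
#' @export
diagonal_search <- function(X, Y, spec, grid = grid_spec(),
                            criterion = criterion_accuracy) {
  X <- as.matrix(X)
  p <- ncol(X)
  out <- numeric(p)
  for (dir in seq_len(p)) {
    best_a <- 0
    best <- grid$candidates[1L]
    lam <- rep(1, p)
    for (cand in grid$candidates) {
      lam[dir] <- cand
      a <- criterion(X, Y, lam, spec)
      if (a > best_a) {
        best_a <- a
        best <- cand
      }
    }
    out[dir] <- best
  }
  out
}

#' Draw a random start point for the iterative search
#'
#' Each coordinate is drawn uniformly over the grid's original bounding
#' interval (the search domain), using the current RNG stream.
#'
#' @param p number of coordinates.
#' @param grid a \code{"bcx_grid"}.
#' @return numeric vector of length \code{p}.
#' @export
generate_initial_point <- function(p, grid = grid_spec()) {
  stats::runif(p, min = grid$domain[1L], max = grid$domain[2L])
}

# Resolve the configured start policy into a concrete exponent vector.
# Constant columns fall back to 1 under the mle policy.
initial_lambda <- function(X, config, grid) {
  p <- ncol(X)
  switch(config$start_policy,
    ones = rep(1, p),
    random = generate_initial_point(p, grid),
    mle = apply(X, 2L, function(col) {
      if (max(col) == min(col)) 1 else mle_lambda(col, interval = grid$domain)
    })
  )
}

#' Iterative coordinate grid search for the exponent vector
#'
#' Full (joint) optimization realized as coordinate descent: per epoch, each
#' direction in the current order is scanned over the candidate grid while
#' the other coordinates are held at the incumbent; the incumbent and the
#' best accuracy update only on strict improvement.  Cost is exactly
#' \code{epochs * p * gridsize} criterion evaluations.  Three optional
#' refinements (periods in \code{config}):
#' \itemize{
#'   \item \strong{shift}: draw a fresh start point and explore from it
#'     until a strict improvement occurs; the exploration base carries the
#'     best coordinate found in each scanned direction.
#'   \item \strong{shuffle}: permute the direction order (the permutation
#'     persists until the next shuffle epoch).
#'   \item \strong{finer}: scale the grid by its \code{finer_factor} and
#'     attach candidates as offsets to the incumbent coordinate.
#' }
#' When several trigger on the same epoch they apply in the order finer,
#' shuffle, shift.
#'
#' @inheritParams grid_search_2d
#' @param config a \code{"bcx_config"}.
#' @return a list with elements \code{lambda} (the incumbent exponent
#'   vector) and \code{trace} (start point, per-evaluation best accuracy,
#'   per-epoch incumbents, evaluation count).
#' @export
iterative_search <- function(X, Y, spec, config = optimizer_config(),
                             grid = grid_spec(gridsize = config$gridsize),
                             criterion = criterion_accuracy) {
  stopifnot(inherits(config, "bcx_config"), inherits(grid, "bcx_grid"))
  X <- as.matrix(X)
  p <- ncol(X)
  withr::with_seed(config$seed, {
    G <- initial_lambda(X, config, grid)
    lambda_opt <- G
    A <- 0
    shift <- FALSE
    base <- NULL
    dir_order <- seq_len(p)
    best_acc <- numeric(0)
    incumbents <- matrix(NA_real_, nrow = config$epochs, ncol = p)

    for (epoch in seq_len(config$epochs)) {
      if (config$use_finer && epoch %% config$finer_epoch == 0L) {
        grid <- refine_grid(grid)
      }
      if (config$use_shuffle && epoch %% config$shuffle_epoch == 0L) {
        dir_order <- sample.int(p)
      }
      if (config$use_shift && epoch %% config$shift_epoch == 0L) {
        G <- generate_initial_point(p, grid)
        base <- G
        shift <- TRUE
      }
      for (dir in dir_order) {
        lam_tmp <- if (shift) base else lambda_opt
        anchor <- lam_tmp[dir]
        cands <- if (grid$mode == "local") {
          grid$candidates + anchor
        } else {
          grid$candidates
        }
        local_a <- -Inf
        local_val <- anchor
        for (cand in cands) {
          lam_tmp[dir] <- cand
          a <- criterion(X, Y, lam_tmp, spec)
          if (a > A) {
            A <- a
            lambda_opt <- lam_tmp
            shift <- FALSE
          }
          if (a > local_a) {
            local_a <- a
            local_val <- cand
          }
          best_acc <- c(best_acc, A)
        }
        if (shift) base[dir] <- local_val
      }
      incumbents[epoch, ] <- lambda_opt
    }
    list(
      lambda = lambda_opt,
      trace = list(start = G, best_accuracy = best_acc,
                   incumbents = incumbents, n_evaluations = length(best_acc),
                   final_accuracy = A)
    )
  })
}

#' Look up an exponent-selection strategy by name
#'
#' @param name one of \code{"identity"} (all ones, no transform beyond the
#'   shift), \code{"mle"}, \code{"spherical"}, \code{"diagonal"},
#'   \code{"grid2d"}, \code{"iterative"}.
#' @return a function \code{(X, Y, spec, config, grid) -> list(lambda, trace)}.
#' @export
get_optimizer <- function(name) {
  switch(name,
    identity = function(X, Y, spec, config, grid)
      list(lambda = rep(1, ncol(X)), trace = NULL),
    mle = function(X, Y, spec, config, grid)
      list(lambda = apply(as.matrix(X), 2L, mle_lambda,
                          interval = grid$domain),
           trace = NULL),
    spherical = function(X, Y, spec, config, grid)
      list(lambda = spherical_search(X, Y, spec, grid), trace = NULL),
    diagonal = function(X, Y, spec, config, grid)
      list(lambda = diagonal_search(X, Y, spec, grid), trace = NULL),
    grid2d = function(X, Y, spec, config, grid)
      list(lambda = grid_search_2d(X, Y, spec, grid), trace = NULL),
    iterative = function(X, Y, spec, config, grid)
      iterative_search(X, Y, spec, config, grid),
    stop(sprintf(
      "unknown optimizer '%s'; valid: identity, mle, spherical, diagonal, grid2d, iterative",
      name))
  )
}
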