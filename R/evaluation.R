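#' Cross-validation configuration
#'
#' @param kfolds number of stratified folds (>= 2), default 10.
#' @param repetitions number of repetitions, default 5.
#' @param base_seed repetition \code{r} (0-based) shuffles with seed
#'   \code{base_seed + r}.
#' @return an object of class \code{"bcx_cvconfig"}.
#' @export
cv_config <- function(kfolds = 10L, repetitions = 5L, base_seed = 42L) {
  if (kfolds < 2L) stop("'kfolds' must be at least 2")
  structure(
    list(kfolds = as.integer(kfolds), repetitions = as.integer(repetitions),
         base_seed = as.integer(base_seed)),
    class = "bcx_cvconfig"
  )
}

#' Stratified k-fold partitions for one repetition
#'
#' Shuffles each class independently (seed \code{base_seed + repetition})
#' and deals its members round-robin into folds, so per-fold class counts
#' differ from exact proportionality by at most one sample.  Test folds are
#' disjoint and jointly cover every sample.
#'
#' @param Y class labels.
#' @param cvconfig a \code{"bcx_cvconfig"}.
#' @param repetition 0-based repetition index.
#' @return list of \code{kfolds} elements, each \code{list(train, test)} of
#'   row indices.
#' @export
stratified_partitions <- function(Y, cvconfig = cv_config(), repetition = 0L) {
  Yc <- as.character(Y)
  k <- cvconfig$kfolds
  counts <- table(Yc)
  small <- names(counts)[counts < k]
  if (length(small) > 0L) {
    stop(sprintf("class '%s' has %d members, fewer than kfolds = %d",
                 small[1L], counts[[small[1L]]], k))
  }
  fold_of <- integer(length(Yc))
  withr::with_seed(cvconfig$base_seed + as.integer(repetition), {
    for (cl in names(counts)) {
      idx <- sample(which(Yc == cl))
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), test = which(fold_of == f))
  })
}

#' Accuracy and F1 score
#'
#' F1 is reported for the designated positive class, by default the
#' lexicographically larger label; \code{average = "macro"} averages the
#' per-class F1 scores instead.
#'
#' @param y_true,y_pred label vectors of equal length.
#' @param positive positive-class label for binary F1 (default: label
#'   sorted last).
#' @param average \code{"binary"} or \code{"macro"}.
#' @return list with elements \code{accuracy} and \code{f1}.
#' @export
metrics <- function(y_true, y_pred, positive = NULL,
                    average = c("binary", "macro")) {
  average <- match.arg(average)
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  acc <- mean(y_true == y_pred)
  f1_for <- function(pos) {
    tp <- sum(y_true == pos & y_pred == pos)
    fp <- sum(y_true != pos & y_pred == pos)
    fn <- sum(y_true == pos & y_pred != pos)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  f1 <- if (average == "binary") {
    if (is.null(positive)) positive <- sort(unique(y_true), decreasing = TRUE)[1L]
    f1_for(positive)
  } else {
    mean(vapply(sort(unique(y_true)), f1_for, numeric(1L)))
  }
  list(accuracy = acc, f1 = f1)
}

#' Repeated stratified cross-validation of the full pipeline
#'
#' For every repetition and fold: fit the complete pipeline (scalers fitted
#' and exponents optimized on the training split only), predict the held-out
#' split, and record accuracy and F1.  The mean accuracy is the sum over all
#' \code{repetitions * kfolds} folds divided by their count.
#'
#' @inheritParams fit_model
#' @param cvconfig a \code{"bcx_cvconfig"}.
#' @return an object of class \code{"bcx_cv"} with the per-fold table and
#'   the mean accuracy / mean F1.
#' @export
evaluate_cv <- function(X, Y, spec = classifier_spec("knn"),
                        optimizer = "identity",
                        config = optimizer_config(),
                        cvconfig = cv_config(),
                        grid = grid_spec(gridsize = config$gridsize)) {
  X <- as.matrix(X)
  rows <- list()
  for (r in seq_len(cvconfig$repetitions) - 1L) {
    parts <- stratified_partitions(Y, cvconfig, repetition = r)
    for (f in seq_along(parts)) {
      tr <- parts[[f]]$train
      te <- parts[[f]]$test
      model <- fit_model(X[tr, , drop = FALSE], Y[tr], spec, optimizer,
                         config, grid)
      pred <- predict(model, X[te, , drop = FALSE])
      m <- metrics(Y[te], pred)
      rows[[length(rows) + 1L]] <- data.frame(
        repetition = r, fold = f, accuracy = m$accuracy, f1 = m$f1)
    }
  }
  folds <- do.call(rbind, rows)
  structure(
    list(folds = folds,
         mean_accuracy = sum(folds$accuracy) /
           (cvconfig$repetitions * cvconfig$kfolds),
         mean_f1 = sum(folds$f1) / (cvconfig$repetitions * cvconfig$kfolds),
         cvconfig = cvconfig),
    class = "bcx_cv"
  )
}

#' Two-dimensional accuracy-heatmap exploration
#'
#' For every exponent pair \eqn{(\lambda_1, \lambda_2)} on the grid, the
#' (already range-standardized) full matrix is Box-Cox transformed, then
#' cross-validated: per fold the standard scaler is fitted on the training
#' split, the classifier trained, and the held-out split scored.  Each cell
#' stores the mean accuracy over \code{repetitions * kfolds} folds.  The
#' fold partitions are seeded per repetition and shared across cells, so the
#' cell at \eqn{\Lambda = [1, 1]} equals the no-transform baseline exactly.
#'
#' @param X feature matrix with exactly 2 columns, range standardized to
#'   \eqn{[1, 2]} (use \code{minmax_apply(minmax_fit(X), X)} first).
#' @param Y class labels.
#' @param spec classifier specification.
#' @param grid a \code{"bcx_grid"} supplying the axis candidates.
#' @param cvconfig a \code{"bcx_cvconfig"}.
#' @return an object of class \code{"bcx_heatmap"}: axis vectors
#'   \code{lambda1} (rows) and \code{lambda2} (columns) and the accuracy
#'   matrix \code{A}.
#' @export
grid_exploration <- function(X, Y, spec = classifier_spec("knn"),
                             grid = grid_spec(), cvconfig = cv_config()) {
  X <- as.matrix(X)
  if (ncol(X) != 2L) stop("grid_exploration requires exactly 2 features")
  axis <- grid$candidates
  parts <- lapply(seq_len(cvconfig$repetitions) - 1L, function(r) {
    stratified_partitions(Y, cvconfig, repetition = r)
  })
  A <- matrix(NA_real_, length(axis), length(axis))
  Yc <- as.character(Y)
  for (i in seq_along(axis)) {
    for (j in seq_along(axis)) {
      Xb <- boxcox_matrix(X, c(axis[i], axis[j]))
      a <- 0
      for (rep_parts in parts) {
        for (part in rep_parts) {
          tr <- part$train
          te <- part$test
          st <- standard_fit(Xb[tr, , drop = FALSE])
          clf <- train_classifier(make_classifier(spec),
                                  standard_apply(st, Xb[tr, , drop = FALSE]),
                                  Y[tr])
          pred <- predict_classifier(clf,
                                     standard_apply(st, Xb[te, , drop = FALSE]))
          a <- a + mean(pred == Yc[te])
        }
      }
      A[i, j] <- a / (cvconfig$repetitions * cvconfig$kfolds)
    }
  }
  structure(list(lambda1 = axis, lambda2 = axis, A = A),
            class = "bcx_heatmap")
}

#' Annotate the spherical, diagonal and full optima on a heatmap
#'
#' \code{full} is the argmax over all cells; \code{spherical} the argmax
#' over the diagonal (\eqn{\lambda_1 = \lambda_2}); \code{diagonal} combines
#' the best \eqn{\lambda_1} along the \eqn{\lambda_2 = 1} column with the
#' best \eqn{\lambda_2} along the \eqn{\lambda_1 = 1} row.  Ties in the
#' diagonal construction are resolved by evaluating every tied combination's
#' joint cell and keeping the best; remaining ties keep the first candidate
#' in scan order (ascending \eqn{\lambda_1} outer, \eqn{\lambda_2} inner).
#'
#' @param heatmap a \code{"bcx_heatmap"} whose axes contain the value 1.
#' @return list with elements \code{full}, \code{spherical},
#'   \code{diagonal}, each \code{list(lambda, accuracy)}.
#' @export
annotate_optima <- function(heatmap) {
  stopifnot(inherits(heatmap, "bcx_heatmap"))
  l1 <- heatmap$lambda1
  l2 <- heatmap$lambda2
  A <- heatmap$A
  i1 <- which(l1 == 1)
  j1 <- which(l2 == 1)
  if (length(i1) != 1L || length(j1) != 1L) {
    stop("heatmap axes must contain the value 1 exactly once")
  }

  # full: first maximizer in row-major scan order
  best <- -Inf; fi <- 1L; fj <- 1L
  for (i in seq_along(l1)) for (j in seq_along(l2)) {
    if (A[i, j] > best) { best <- A[i, j]; fi <- i; fj <- j }
  }
  full <- list(lambda = c(l1[fi], l2[fj]), accuracy = best)

  # spherical: first maximizer on the diagonal
  if (length(l1) != length(l2)) stop("spherical annotation needs a square grid")
  d <- vapply(seq_along(l1), function(i) A[i, i], numeric(1L))
  si <- which.max(d)
  spherical <- list(lambda = c(l1[si], l2[si]), accuracy = d[si])

  # diagonal: per-axis winners with the other coordinate fixed at 1;
  # tied winners resolved by the best joint cell
  col1 <- A[, j1]
  row1 <- A[i1, ]
  cand_i <- which(col1 == max(col1))
  cand_j <- which(row1 == max(row1))
  best <- -Inf; di <- cand_i[1L]; dj <- cand_j[1L]
  for (i in cand_i) for (j in cand_j) {
    if (A[i, j] > best) { best <- A[i, j]; di <- i; dj <- j }
  }
  diagonal <- list(lambda = c(l1[di], l2[dj]), accuracy = A[di, dj])

  list(full = full, spherical = spherical, diagonal = diagonal)
}

#' Before/after accuracy deltas against a baseline
#'
#' Reports, for each optimization strategy, its mean CV accuracy and the
#' improvement over the baseline, both on the percent scale.  Deltas are
#' computed at full precision; rounding is left to rendering.
#'
#' @param results named list of \code{"bcx_cv"} results, one per strategy.
#' @param baseline the baseline \code{"bcx_cv"} (no transform,
#'   \eqn{\Lambda = 1}).
#' @return data frame with columns \code{strategy}, \code{accuracy}
#'   (percent) and \code{delta} (percentage points vs baseline).
#' @export
delta_table <- function(results, baseline) {
  stopifnot(inherits(baseline, "bcx_cv"))
  n_base <- nrow(baseline$folds)
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    stopifnot(inherits(r, "bcx_cv"))
    if (nrow(r$folds) != n_base) {
      stop(sprintf("strategy '%s' has %d folds but the baseline has %d",
                   nm, nrow(r$folds), n_base))
    }
    data.frame(strategy = nm,
               accuracy = 100 * r$mean_accuracy,
               delta = 100 * (r$mean_accuracy - baseline$mean_accuracy))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a heatmap as CSV with explicit axes
#'
#' First column holds the \eqn{\lambda_1} (row) axis; the header row holds
#' the \eqn{\lambda_2} (column) axis.
#'
#' @param heatmap a \code{"bcx_heatmap"}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_heatmap_csv <- function(heatmap, path) {
  stopifnot(inherits(heatmap, "bcx_heatmap"))
  df <- data.frame(lambda1 = heatmap$lambda1, heatmap$A, check.names = FALSE)
  names(df) <- c("lambda1", as.character(heatmap$lambda2))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
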