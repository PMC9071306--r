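#' Fit the Box-Cox classification pipeline
#'
#' Executes the training stages in fixed order: fit and apply the min-max
#' scaler into \eqn{[1, 2]} (guaranteeing positivity), select the exponent
#' vector with the chosen optimizer on the scaled data, apply the Box-Cox
#' transform, fit and apply the standard scaler, and finally train the
#' classifier.  Standardization never precedes the transform: standardized
#' data is not positive.
#'
#' @param X numeric feature matrix (n samples x p features).
#' @param Y class labels (>= 2 distinct values expected; a single-class
#'   input degenerates the criterion, triggers a warning, and falls back to
#'   the all-ones exponent vector).
#' @param spec a \code{"bcx_spec"} classifier specification (or name).
#' @param optimizer strategy name understood by \code{\link{get_optimizer}},
#'   or a function with the same contract.
#' @param config a \code{"bcx_config"} (used by the iterative strategy).
#' @param grid a \code{"bcx_grid"}.
#' @return an object of class \code{"bcx_model"} bundling the exponent
#'   vector, the trained classifier, both fitted scalers, the optimizer
#'   name/config, and the search trace when one exists.
#' @export
fit_model <- function(X, Y, spec = classifier_spec("knn"),
                      optimizer = "iterative",
                      config = optimizer_config(),
                      grid = grid_spec(gridsize = config$gridsize)) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  X <- as.matrix(X)
  opt_name <- if (is.character(optimizer)) optimizer else "custom"
  opt_fun <- if (is.character(optimizer)) get_optimizer(optimizer) else optimizer

  mm <- minmax_fit(X)
  Xm <- minmax_apply(mm, X)
  if (length(unique(as.character(Y))) < 2L) {
    warning("only one class present; exponent optimization is degenerate, using lambda = 1")
    res <- list(lambda = rep(1, ncol(X)), trace = NULL)
  } else {
    res <- opt_fun(Xm, Y, spec, config, grid)
  }
  Xb <- boxcox_matrix(Xm, res$lambda)
  st <- standard_fit(Xb)
  Xs <- standard_apply(st, Xb)
  clf <- train_classifier(make_classifier(spec), Xs, Y)
  structure(
    list(lambda = res$lambda, classifier = clf, minmax = mm, standard = st,
         optimizer = opt_name, config = config, trace = res$trace),
    class = "bcx_model"
  )
}

#' Predict labels with a fitted pipeline
#'
#' Mirrors the training path using the stored state only: the fitted min-max
#' scaler, the optimized exponent vector, the fitted standard scaler, and
#' the trained classifier.  No component is refitted.
#'
#' @param object a \code{"bcx_model"}.
#' @param newdata feature matrix with the training column count.
#' @param ... unused.
#' @return character vector of predicted labels.
#' @export
predict.bcx_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$lambda)) {
    stop(sprintf("model was fitted on %d features, data has %d",
                 length(object$lambda), ncol(newdata)))
  }
  Xm <- minmax_apply(object$minmax, newdata)
  Xb <- boxcox_matrix(Xm, object$lambda)
  Xs <- standard_apply(object$standard, Xb)
  predict_classifier(object$classifier, Xs)
}

#' @export
print.bcx_model <- function(x, ...) {
  cat("Box-Cox classification pipeline\n")
  cat("  classifier:", x$classifier$spec$name, "\n")
  cat("  optimizer: ", x$optimizer, "\n")
  cat("  lambda:    ", paste(signif(x$lambda, 4L), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize the transform state of a fitted pipeline to JSON
#'
#' Writes the exponent vector, both scaler states, and the optimizer
#' configuration.  The trained classifier itself is not serialized (refit
#' from data when needed); the JSON captures everything required to
#' reproduce the transform.
#'
#' @param model a \code{"bcx_model"}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
save_model_json <- function(model, path) {
  stopifnot(inherits(model, "bcx_model"))
  payload <- list(
    lambda = model$lambda,
    minmax = list(min = model$minmax$min, max = model$minmax$max),
    standard = list(mean = model$standard$mean, sd = model$standard$sd),
    optimizer = model$optimizer,
    config = unclass(model$config),
    classifier = unclass(model$classifier$spec)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
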