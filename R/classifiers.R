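#' Specify one of the five reference classifiers
#'
#' Closed set of classifier families used throughout the package:
#' \describe{
#'   \item{linear}{linear classifier with perceptron loss, trained by
#'     stochastic gradient descent (one-vs-rest for >2 classes).}
#'   \item{knn}{k-nearest-neighbour vote, default \code{k = 5}.}
#'   \item{bayesian}{Gaussian naive Bayes.}
#'   \item{svc}{C-support vector machine with radial-basis kernel.}
#'   \item{nn}{multilayer network with two hidden layers of 10 rectified
#'     linear units each, softmax cross-entropy output.}
#' }
#'
#' @param name one of \code{"linear"}, \code{"knn"}, \code{"bayesian"},
#'   \code{"svc"}, \code{"nn"}.
#' @param k neighbour count for \code{knn}.
#' @param hidden integer vector of hidden-layer widths for \code{nn}.
#' @param kernel kernel name for \code{svc} (passed to \code{e1071::svm}).
#' @param seed integer seed applied to every stochastic component.
#' @return an object of class \code{"bcx_spec"}.
#' @export
classifier_spec <- function(name, k = 5L, hidden = c(10L, 10L),
                            kernel = "radial", seed = 42L) {
  valid <- c("linear", "knn", "bayesian", "svc", "nn")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid)) {
    stop(sprintf("unknown classifier '%s'; valid names: %s",
                 as.character(name)[1L], paste(valid, collapse = ", ")))
  }
  structure(
    list(name = name, k = as.integer(k), hidden = as.integer(hidden),
         kernel = kernel, seed = as.integer(seed)),
    class = "bcx_spec"
  )
}

#' Instantiate an untrained classifier handle from a spec
#'
#' @param spec a \code{"bcx_spec"} object (or a classifier name, which is
#'   promoted with default hyperparameters).
#' @return an object of class \code{"bcx_classifier"} exposing
#'   \code{\link{train_classifier}} and \code{\link{predict_classifier}}.
#' @export
make_classifier <- function(spec) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  stopifnot(inherits(spec, "bcx_spec"))
  structure(
    list(spec = spec, model = NULL, levels = NULL, trained = FALSE),
    class = "bcx_classifier"
  )
}

#' Train a classifier handle
#'
#' @param clf handle from \code{\link{make_classifier}}.
#' @param X numeric feature matrix.
#' @param Y class labels (any atomic type; coerced to factor internally).
#' @return the trained handle.
#' @export
train_classifier <- function(clf, X, Y) {
  stopifnot(inherits(clf, "bcx_classifier"))
  X <- as.matrix(X)
  Yf <- factor(Y)
  if (nrow(X) != length(Yf)) stop("X and Y disagree on the number of samples")
  spec <- clf$spec
  clf$levels <- levels(Yf)
  clf$p <- ncol(X)
  clf$model <- switch(spec$name,
    knn = list(X = X, Y = Yf),
    bayesian = e1071::naiveBayes(x = as.data.frame(X), y = Yf),
    svc = e1071::svm(x = X, y = Yf, type = "C-classification",
                     kernel = spec$kernel, scale = FALSE),
    linear = perceptron_fit(X, Yf, seed = spec$seed),
    nn = mlp_fit(X, Yf, hidden = spec$hidden, seed = spec$seed)
  )
  clf$trained <- TRUE
  clf
}

#' Predict labels with a trained classifier handle
#'
#' @param clf a trained handle.
#' @param X numeric feature matrix with the training column count.
#' @return character vector of predicted labels, drawn from the training
#'   label set.
#' @export
predict_classifier <- function(clf, X) {
  stopifnot(inherits(clf, "bcx_classifier"))
  if (!isTRUE(clf$trained)) stop("classifier has not been trained yet")
  X <- as.matrix(X)
  if (ncol(X) != clf$p) {
    stop(sprintf("classifier was trained on %d features, data has %d",
                 clf$p, ncol(X)))
  }
  pred <- switch(clf$spec$name,
    knn = class::knn(clf$model$X, X, clf$model$Y, k = clf$spec$k),
    bayesian = stats::predict(clf$model, as.data.frame(X)),
    svc = stats::predict(clf$model, X),
    linear = perceptron_predict(clf$model, X),
    nn = mlp_predict(clf$model, X)
  )
  as.character(pred)
}
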