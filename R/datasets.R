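#' Generate a synthetic 2-D binary classification dataset
#'
#' Four families of two-feature, two-class problems for studying the effect
#' of the transform:
#' \describe{
#'   \item{gaussian_quantiles}{standard bivariate Gaussian split into an
#'     inner and an outer class by the median squared radius (concentric
#'     shells).}
#'   \item{half_circles}{two interleaving half circles with optional
#'     additive Gaussian noise (default 0).}
#'   \item{blobs}{two isotropic Gaussian clusters with randomly placed
#'     centers in \eqn{[-10, 10]^2}.}
#'   \item{random_linear}{two informative Gaussian clusters at
#'     \eqn{\pm}\code{class_sep} per coordinate, passed through a random
#'     linear mixing matrix.}
#' }
#' All families are deterministic for a fixed seed and produce classes
#' balanced within one sample.
#'
#' @param family one of the four family names.
#' @param n_samples total sample count (>= 20).
#' @param noise standard deviation of additive noise (half circles).
#' @param spread cluster standard deviation (blobs).
#' @param class_sep cluster separation per coordinate (random_linear).
#' @param seed integer seed.
#' @return list with elements \code{X} (n x 2 matrix, columns
#'   \code{f1, f2}) and \code{Y} (integer labels 0/1).
#' @export
make_synthetic <- function(family = c("gaussian_quantiles", "half_circles",
                                      "blobs", "random_linear"),
                           n_samples = 1000L, noise = 0, spread = 1.5,
                           class_sep = 1.0, seed = 42L) {
  family <- match.arg(family)
  n <- as.integer(n_samples)
  if (n < 20L) stop("'n_samples' must be at least 20")
  out <- withr::with_seed(as.integer(seed), {
    switch(family,
      gaussian_quantiles = {
        X <- matrix(stats::rnorm(2L * n), n, 2L)
        r2 <- rowSums(X^2)
        Y <- integer(n)
        Y[order(r2)[seq_len(ceiling(n / 2))]] <- 0L
        Y[order(r2)[-seq_len(ceiling(n / 2))]] <- 1L
        list(X = X, Y = Y)
      },
      half_circles = {
        n_out <- n %/% 2L
        n_in <- n - n_out
        t_out <- seq(0, pi, length.out = n_out)
        t_in <- seq(0, pi, length.out = n_in)
        X <- rbind(
          cbind(cos(t_out), sin(t_out)),
          cbind(1 - cos(t_in), 1 - sin(t_in) - 0.5)
        )
        if (noise > 0) X <- X + matrix(stats::rnorm(2L * n, sd = noise), n, 2L)
        list(X = X, Y = rep(c(0L, 1L), c(n_out, n_in)))
      },
      blobs = {
        centers <- matrix(stats::runif(4L, -10, 10), 2L, 2L)
        n0 <- n %/% 2L
        n1 <- n - n0
        X <- rbind(
          matrix(stats::rnorm(2L * n0, sd = spread), n0, 2L) +
            matrix(centers[1L, ], n0, 2L, byrow = TRUE),
          matrix(stats::rnorm(2L * n1, sd = spread), n1, 2L) +
            matrix(centers[2L, ], n1, 2L, byrow = TRUE)
        )
        list(X = X, Y = rep(c(0L, 1L), c(n0, n1)))
      },
      random_linear = {
        n0 <- n %/% 2L
        n1 <- n - n0
        X <- matrix(stats::rnorm(2L * n), n, 2L)
        X[seq_len(n0), ] <- X[seq_len(n0), ] - class_sep
        X[-seq_len(n0), ] <- X[-seq_len(n0), ] + class_sep
        mix <- matrix(stats::runif(4L, -1, 1), 2L, 2L)
        list(X = X %*% mix, Y = rep(c(0L, 1L), c(n0, n1)))
      }
    )
  })
  colnames(out$X) <- c("f1", "f2")
  out
}

#' Load a tabular classification dataset from CSV
#'
#' Auto-detects comma vs semicolon delimiters.  Every non-label column must
#' be numeric; rows containing missing values are rejected with a count.
#'
#' @param path CSV file path.
#' @param label_column label column name or index (default \code{"y"}).
#' @param header whether the file has a header row.
#' @return list with elements \code{X} (numeric matrix) and \code{Y}
#'   (character labels).
#' @export
load_tabular <- function(path, label_column = "y", header = TRUE) {
  first <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(first, gregexpr(";", first))) >
             lengths(regmatches(first, gregexpr(",", first)))) ";" else ","
  df <- utils::read.csv(path, sep = sep, header = header,
                        stringsAsFactors = FALSE)
  if (is.numeric(label_column)) {
    if (label_column < 1L || label_column > ncol(df)) {
      stop(sprintf("label column index %d out of range", label_column))
    }
    lab <- label_column
  } else {
    lab <- match(label_column, names(df))
    if (is.na(lab)) stop(sprintf("label column '%s' not found", label_column))
  }
  Y <- as.character(df[[lab]])
  feats <- df[-lab]
  for (j in seq_along(feats)) {
    if (!is.numeric(feats[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(feats[[j]]))) &
                   !is.na(feats[[j]]))[1L]
      stop(sprintf("non-numeric value in feature column '%s' (row %d)",
                   names(feats)[j], if (is.na(bad)) 1L else bad))
    }
  }
  X <- as.matrix(feats)
  miss <- which(rowSums(is.na(X)) > 0 | is.na(Y))
  if (length(miss) > 0L) {
    stop(sprintf("%d row(s) contain missing values (rows: %s)",
                 length(miss),
                 paste(utils::head(miss, 10L), collapse = ", ")))
  }
  list(X = X, Y = Y)
}

#' Rank features by the chi-square statistic
#'
#' Computes, per feature, the chi-square statistic of the class-wise feature
#' sums against their expectation under independence of feature magnitude
#' and class label (the standard non-negative-feature univariate screen).
#' Features are returned sorted by decreasing statistic; ties keep the
#' original column order.
#'
#' @param X non-negative feature matrix.
#' @param Y class labels.
#' @return integer vector: column indices in decreasing relevance order.
#' @export
chi2_rank <- function(X, Y) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("chi-square ranking requires non-negative features")
  Yf <- factor(Y)
  class_prob <- as.numeric(table(Yf)) / length(Yf)
  stat <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    obs <- tapply(X[, j], Yf, sum)
    exp_ <- class_prob * sum(X[, j])
    stat[j] <- sum((obs - exp_)^2 / exp_)
  }
  order(-stat)
}

#' Extract a two-feature subset
#'
#' @param X feature matrix.
#' @param i,j distinct column indices.
#' @param Y optional labels, passed through unchanged.
#' @return list with the 2-column matrix \code{X} (row order preserved) and
#'   \code{Y}.
#' @export
extract_feature_pair <- function(X, i, j, Y = NULL) {
  X <- as.matrix(X)
  if (i == j) stop("feature indices must be distinct")
  if (any(c(i, j) < 1L) || any(c(i, j) > ncol(X))) {
    stop(sprintf("feature index out of range 1..%d", ncol(X)))
  }
  list(X = X[, c(i, j), drop = FALSE], Y = Y)
}

#' Write a dataset as CSV
#'
#' Features are written as columns \code{f1, f2, ...} with the labels in a
#' final column \code{y}.
#'
#' @param data list with \code{X} and \code{Y}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_dataset_csv <- function(data, path) {
  df <- as.data.frame(data$X)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$y <- data$Y
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
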