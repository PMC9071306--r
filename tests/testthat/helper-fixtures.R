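# Fixtures are generated in code; all are seeded.

# two well-separated Gaussian point clouds (labels "a"/"b")
sep_clouds <- function(n_per = 10L, sep = 10, seed = 7L, p = 2L) {
  withr::with_seed(seed, {
    X <- rbind(
      matrix(stats::rnorm(n_per * p), n_per, p),
      matrix(stats::rnorm(n_per * p, mean = sep), n_per, p)
    )
    list(X = X, Y = rep(c("a", "b"), each = n_per))
  })
}

# small overlapping 2-class fixture where accuracy is not saturated
overlap_fixture <- function(n_per = 15L, sep = 1.2, seed = 11L) {
  sep_clouds(n_per = n_per, sep = sep, seed = seed)
}

# range-standardize to [1, 2]
range_std <- function(X) minmax_apply(minmax_fit(X), X)

# independent re-implementation of the in-sample criterion for a 5-NN vote:
# Box-Cox, standardize, then for each point take the 5 nearest training
# points (self included) and vote; first level wins ties.
oracle_knn_criterion <- function(X, Y, lambda, k = 5L) {
  Xb <- apply_boxcox_by_loop(X, lambda)
  mu <- colMeans(Xb)
  sdev <- sqrt(colMeans(sweep(Xb, 2, mu)^2))
  Xs <- sweep(sweep(Xb, 2, mu), 2, sdev, "/")
  D <- as.matrix(dist(Xs))
  pred <- vapply(seq_len(nrow(Xs)), function(i) {
    nb <- order(D[i, ])[seq_len(k)]
    tab <- table(Y[nb])
    names(tab)[which.max(tab)]
  }, character(1))
  mean(pred == Y)
}

# element-wise loop oracle for the matrix transform
apply_boxcox_by_loop <- function(X, lambda) {
  out <- X
  for (j in seq_len(ncol(X))) {
    for (i in seq_len(nrow(X))) {
      out[i, j] <- if (lambda[j] == 0) log(X[i, j]) else
        (X[i, j]^lambda[j] - 1) / lambda[j]
    }
  }
  out
}

# lookup-table criterion over integer candidate coordinates
table_criterion <- function(tab, cands) {
  function(X, Y, lambda, spec) {
    tab[match(lambda[1], cands), match(lambda[2], cands)]
  }
}
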