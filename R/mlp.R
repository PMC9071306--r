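# Multilayer feed-forward network: rectified-linear hidden layers, softmax
# output, cross-entropy loss, full-batch Adam. He-normal initialization is
# drawn in R under the configured seed; the compiled training loop
# (src/mlp.cpp) is deterministic. Sized for the small tabular problems this
# package targets (two hidden layers of 10 units by default).

mlp_fit <- function(X, Yf, hidden = c(10L, 10L), seed = 42L,
                    lr = 0.01, maxit = 200L,
                    beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  n <- nrow(X); K <- nlevels(Yf)
  sizes <- c(ncol(X), hidden, K)
  L <- length(sizes) - 1L
  Yk <- matrix(0, n, K)
  Yk[cbind(seq_len(n), as.integer(Yf))] <- 1

  init <- withr::with_seed(seed, {
    lapply(seq_len(L), function(l) {
      list(W = matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                   sd = sqrt(2 / sizes[l])),
                      sizes[l], sizes[l + 1L]),
           b = rep(0, sizes[l + 1L]))
    })
  })
  fit <- mlp_train_cpp(X, Yk,
                       lapply(init, `[[`, "W"), lapply(init, `[[`, "b"),
                       lr, as.integer(maxit), beta1, beta2, eps)
  list(W = fit$W, b = fit$b, levels = levels(Yf))
}

mlp_predict <- function(model, X) {
  L <- length(model$W)
  A <- X
  for (l in seq_len(L)) {
    Z <- sweep(A %*% model$W[[l]], 2L, model$b[[l]], "+")
    A <- if (l < L) pmax(Z, 0) else Z
  }
  model$levels[max.col(A, ties.method = "first")]
}
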