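# Linear classifier with perceptron loss, fitted by sequential SGD
# (one binary perceptron per class, one-vs-rest; argmax decision).
# Hyperparameters follow the common library defaults: learning rate 1,
# up to 1000 shuffled epochs, early stop when the training mistake rate
# fails to improve by 1e-3 for 5 consecutive epochs.

perceptron_fit <- function(X, Yf, seed = 42L,
                           max_iter = 1000L, tol = 1e-3, patience = 5L) {
  K <- nlevels(Yf)
  y0 <- as.integer(Yf) - 1L
  W <- withr::with_seed(seed,
    perceptron_train_cpp(X, y0, K, max_iter, tol, patience))
  list(W = W, levels = levels(Yf))
}

perceptron_predict <- function(model, X) {
  p <- nrow(model$W) - 1L
  scores <- cbind(X, 1) %*% model$W
  model$levels[max.col(scores, ties.method = "first")]
}
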