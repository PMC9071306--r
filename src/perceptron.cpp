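#include <Rcpp.h>
using namespace Rcpp;

// One-vs-rest perceptron training. Targets arrive as a 0-based integer class
// index; weights are a (p+1) x K matrix (last row = bias). Classic update:
// on a mistake for binary target t in {-1,+1}, w += t * x. Epochs shuffle the
// sample order using R's RNG (caller seeds it); training stops early when the
// mistake rate fails to improve by `tol` for `patience` consecutive epochs.
// [[Rcpp::export]]
NumericMatrix perceptron_train_cpp(NumericMatrix X, IntegerVector y, int K,
                                   int max_iter, double tol, int patience) {
  int n = X.nrow(), p = X.ncol();
  NumericMatrix W(p + 1, K);
  double best = R_PosInf;
  int no_change = 0;

  IntegerVector idx = seq(0, n - 1);
  for (int epoch = 0; epoch < max_iter; ++epoch) {
    IntegerVector ord = sample(idx, n, false);
    int mistakes = 0;
    for (int ii = 0; ii < n; ++ii) {
      int i = ord[ii];
      bool wrong = false;
      for (int k = 0; k < K; ++k) {
        double score = W(p, k);
        for (int j = 0; j < p; ++j) score += W(j, k) * X(i, j);
        double t = (y[i] == k) ? 1.0 : -1.0;
        if (t * score <= 0) {
          wrong = true;
          for (int j = 0; j < p; ++j) W(j, k) += t * X(i, j);
          W(p, k) += t;
        }
      }
      if (wrong) ++mistakes;
    }
    double loss = (double)mistakes / n;
    if (loss == 0.0) break;
    if (loss > best - tol) {
      if (++no_change >= patience) break;
    } else {
      no_change = 0;
    }
    if (loss < best) best = loss;
  }
  return W;
}
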