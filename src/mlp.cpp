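// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Full-batch Adam training of a ReLU feed-forward network with softmax
// cross-entropy loss. Initial weights arrive from R (seeded there); the
// optimization itself is deterministic.
// [[Rcpp::export]]
List mlp_train_cpp(const arma::mat& X, const arma::mat& Yk, List W0, List b0,
                   double lr, int maxit, double beta1, double beta2,
                   double eps) {
  int L = W0.size();
  int n = X.n_rows;
  std::vector<arma::mat> W(L), mW(L), vW(L);
  std::vector<arma::rowvec> b(L), mb(L), vb(L);
  for (int l = 0; l < L; ++l) {
    W[l] = as<arma::mat>(W0[l]);
    b[l] = as<arma::rowvec>(b0[l]);
    mW[l].zeros(W[l].n_rows, W[l].n_cols);
    vW[l].zeros(W[l].n_rows, W[l].n_cols);
    mb[l].zeros(b[l].n_elem);
    vb[l].zeros(b[l].n_elem);
  }
  std::vector<arma::mat> A(L + 1);
  for (int t = 1; t <= maxit; ++t) {
    // forward
    A[0] = X;
    for (int l = 0; l < L; ++l) {
      arma::mat Z = A[l] * W[l];
      Z.each_row() += b[l];
      A[l + 1] = (l < L - 1) ? arma::clamp(Z, 0.0, arma::datum::inf) : Z;
    }
    // softmax gradient
    arma::mat Z = A[L];
    Z.each_col() -= arma::max(Z, 1);
    arma::mat P = arma::exp(Z);
    P.each_col() /= arma::sum(P, 1);
    arma::mat delta = (P - Yk) / n;
    // backward + Adam
    double c1 = 1.0 - std::pow(beta1, t);
    double c2 = 1.0 - std::pow(beta2, t);
    for (int l = L - 1; l >= 0; --l) {
      arma::mat gW = A[l].t() * delta;
      arma::rowvec gb = arma::sum(delta, 0);
      if (l > 0) {
        delta = (delta * W[l].t()) % arma::conv_to<arma::mat>::from(A[l] > 0);
      }
      mW[l] = beta1 * mW[l] + (1 - beta1) * gW;
      vW[l] = beta2 * vW[l] + (1 - beta2) * (gW % gW);
      mb[l] = beta1 * mb[l] + (1 - beta1) * gb;
      vb[l] = beta2 * vb[l] + (1 - beta2) * (gb % gb);
      W[l] -= lr * (mW[l] / c1) / (arma::sqrt(vW[l] / c2) + eps);
      b[l] -= lr * (mb[l] / c1) / (arma::sqrt(vb[l] / c2) + eps);
    }
  }
  List Wout(L), bout(L);
  for (int l = 0; l < L; ++l) {
    Wout[l] = W[l];
    bout[l] = NumericVector(b[l].begin(), b[l].end());
  }
  return List::create(_["W"] = Wout, _["b"] = bout);
}
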