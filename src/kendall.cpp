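// Kendall's tau-a: the unnormalized-for-ties pairwise concordance statistic
//   tau = 2/(n(n-1)) * sum_{i<i'} sign(x_i - x_i') * sign(y_i - y_i').
// Tied pairs contribute zero, which is exactly what the latent-copula bridge
// functions assume for binary and mixed pairs (tau-b's tie normalization
// would break the bridge identities).

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

static inline double sgn(double x) { return (x > 0) - (x < 0); }

// [[Rcpp::export]]
double cpp_kendall_tau_a(NumericVector x, NumericVector y) {
  R_xlen_t n = x.size();
  double s = 0.0;
  for (R_xlen_t i = 0; i < n - 1; i++)
    for (R_xlen_t j = i + 1; j < n; j++)
      s += sgn(x[i] - x[j]) * sgn(y[i] - y[j]);
  return 2.0 * s / (double(n) * double(n - 1));
}

// tau-a for every pair of columns of X (n x p), returned as a p x p matrix
// with unit diagonal.
// [[Rcpp::export]]
NumericMatrix cpp_kendall_tau_a_matrix(NumericMatrix X) {
  int n = X.nrow(), p = X.ncol();
  NumericMatrix out(p, p);
  // precompute pairwise sign matrices column by column would need O(n^2 p)
  // memory; instead loop pairs with a cache of the current column's signs.
  std::vector<double> sj(((size_t)n * (n - 1)) / 2);
  for (int j = 0; j < p; j++) {
    size_t idx = 0;
    for (int i = 0; i < n - 1; i++)
      for (int i2 = i + 1; i2 < n; i2++)
        sj[idx++] = sgn(X(i, j) - X(i2, j));
    for (int k = j; k < p; k++) {
      if (k == j) { out(j, j) = 1.0; continue; }
      double s = 0.0;
      size_t id2 = 0;
      for (int i = 0; i < n - 1; i++)
        for (int i2 = i + 1; i2 < n; i2++) {
          s += sj[id2] * sgn(X(i, k) - X(i2, k));
          id2++;
        }
      double tau = 2.0 * s / (double(n) * double(n - 1));
      out(j, k) = tau;
      out(k, j) = tau;
    }
  }
  return out;
}
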