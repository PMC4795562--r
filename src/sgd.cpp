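#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Stochastic gradient descent for unregularized logistic regression on a
// sparse design matrix in CSR form (xp: row pointers, xi: 0-based column
// indices, xv: values). Weights start at zero; each epoch visits the
// examples in a freshly shuffled order drawn from R's RNG, so results are
// reproducible under set.seed(). Update: w += lr * (y - sigmoid(w.x + b)) x.
// [[Rcpp::export]]
NumericVector sgd_fit_cpp(IntegerVector xp, IntegerVector xi,
                          NumericVector xv, NumericVector y,
                          int n_features, double lr, int epochs) {
  const int n = y.size();
  NumericVector w(n_features + 1); // last entry is the intercept
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = n - 1; i > 0; --i) { // Fisher-Yates via R RNG
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(ord[i], ord[j]);
    }
    for (int k = 0; k < n; ++k) {
      const int r = ord[k];
      double z = w[n_features];
      for (int p = xp[r]; p < xp[r + 1]; ++p) z += w[xi[p]] * xv[p];
      const double s = 1.0 / (1.0 + std::exp(-z));
      const double g = lr * (y[r] - s);
      for (int p = xp[r]; p < xp[r + 1]; ++p) w[xi[p]] += g * xv[p];
      w[n_features] += g;
    }
  }
  return w;
}
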