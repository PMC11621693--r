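#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Unnormalised Gaussian kernel sums at every sample point, self-term
// included: out[i] = sum_j exp(-|x_i - x_j|^2 / (2 sigma^2)).
// Symmetric, so each pair is computed once.  The caller applies the
// (2 pi sigma^2)^(-n/2) / M normalisation.
// [[Rcpp::export]]
NumericVector kde_gauss_sum(NumericMatrix x, double sigma) {
  const int m = x.nrow(), n = x.ncol();
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  NumericVector out(m, 1.0);  // self-term: exp(0) = 1
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j < m; ++j) {
      double d2 = 0.0;
      for (int k = 0; k < n; ++k) {
        const double d = x(i, k) - x(j, k);
        d2 += d * d;
      }
      const double e = std::exp(-d2 * inv2s2);
      out[i] += e;
      out[j] += e;
    }
  }
  return out;
}
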