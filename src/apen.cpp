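#include <Rcpp.h>
using namespace Rcpp;

// Approximate entropy with Chebyshev distance and self-matches included:
// ApEn(m, r) = Phi_m(r) - Phi_{m+1}(r), where
// Phi_m(r) = mean_i log( C_i^m(r) ), C_i^m = (# j with d(X_i, X_j) <= r) / (N - m + 1)
// and X_i are the m-length delay vectors. The O(N^2) pair scan lives here
// because the density sequences it runs on are hundreds of points long and
// the feature is computed once per channel-window.

static double phi(const NumericVector& x, int m, double r) {
  const int n = x.size() - m + 1;
  double acc = 0.0;
  for (int i = 0; i < n; ++i) {
    int count = 0;
    for (int j = 0; j < n; ++j) {
      double dmax = 0.0;
      for (int k = 0; k < m; ++k) {
        double d = std::fabs(x[i + k] - x[j + k]);
        if (d > dmax) dmax = d;
        if (dmax > r) break;
      }
      if (dmax <= r) ++count;
    }
    acc += std::log((double)count / n);
  }
  return acc / n;
}

// [[Rcpp::export(name = ".apen_cpp")]]
double apen_cpp(NumericVector x, int m, double r) {
  if (x.size() < m + 2) stop("sequence too short for ApEn");
  return phi(x, m, r) - phi(x, m + 1, r);
}
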