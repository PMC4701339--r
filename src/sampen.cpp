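#include <Rcpp.h>
using namespace Rcpp;

// Ordered template-pair counts for sample entropy.
//
// Both the m-point count B and the (m+1)-point count A use the same
// template set i = 1..N-m (so every template has a defined (m+1)-th point),
// Chebyshev distance, self-matches excluded.  Counts are returned as
// doubles to avoid integer overflow on long series.
// [[Rcpp::export]]
List sampen_counts_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  if (m < 1) stop("`m` must be >= 1");
  if (r <= 0) stop("`r` must be > 0");
  if (n < m + 2) stop("series must have at least m + 2 samples");
  const int nt = n - m;
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double dmax = 0.0;
      for (int l = 0; l < m; ++l) {
        double d = std::fabs(x[i + l] - x[j + l]);
        if (d > dmax) {
          dmax = d;
          if (dmax > r) break;
        }
      }
      if (dmax <= r) {
        B += 2.0;  // ordered pairs: (i,j) and (j,i)
        if (std::fabs(x[i + m] - x[j + m]) <= r) A += 2.0;
      }
    }
  }
  return List::create(_["A"] = A, _["B"] = B);
}
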