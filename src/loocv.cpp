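#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <limits>
using namespace Rcpp;

// Leave-one-out predictions for the three nearest-neighbour rules
// (lmknn, pnn, lmpnn) at every k = 1..k_max in one pass.
//
// cls holds 1-based class indices; class-score ties go to the lower class
// index (earlier level), neighbour distance ties to the lower training row.
// k beyond a class's fold size reuses the truncated-k score.
//
// Returns an integer vector laid out as [n x k_max x 3] (column-major:
// i + n*(k-1) + n*k_max*(method-1)), methods ordered lmknn, pnn, lmpnn.
// [[Rcpp::export]]
IntegerVector loocv_preds_cpp(NumericMatrix X, IntegerVector cls,
                              int n_class, int k_max) {
  const int n = X.nrow(), d = X.ncol();
  const double inf = std::numeric_limits<double>::infinity();

  // full Euclidean distance matrix
  std::vector<double> D((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int l = 0; l < d; ++l) {
        double diff = X(i, l) - X(j, l);
        s += diff * diff;
      }
      double dist = std::sqrt(s);
      D[(size_t)i * n + j] = dist;
      D[(size_t)j * n + i] = dist;
    }
  }

  IntegerVector out((size_t)n * k_max * 3);
  std::vector<int> members;
  std::vector<std::pair<double, int> > ord;
  std::vector<double> csum(d), ds(k_max), dloc(k_max);
  std::vector<double> best_lm(k_max), best_pn(k_max), best_lp(k_max);
  std::vector<int> arg_lm(k_max), arg_pn(k_max), arg_lp(k_max);

  for (int i = 0; i < n; ++i) {
    std::fill(best_lm.begin(), best_lm.end(), inf);
    std::fill(best_pn.begin(), best_pn.end(), inf);
    std::fill(best_lp.begin(), best_lp.end(), inf);

    for (int c = 1; c <= n_class; ++c) {
      ord.clear();
      for (int j = 0; j < n; ++j) {
        if (j != i && cls[j] == c) ord.push_back(std::make_pair(D[(size_t)i * n + j], j));
      }
      if (ord.empty()) stop("a training fold lost a class entirely");
      // stable sort on distance keeps ascending row index on exact ties
      std::stable_sort(ord.begin(), ord.end(),
                       [](const std::pair<double, int> &a,
                          const std::pair<double, int> &b) {
                         return a.first < b.first;
                       });
      int kk = std::min<int>(k_max, (int)ord.size());
      std::fill(csum.begin(), csum.end(), 0.0);
      for (int j = 0; j < kk; ++j) {
        ds[j] = ord[j].first;
        int row = ord[j].second;
        double s = 0.0;
        for (int l = 0; l < d; ++l) {
          csum[l] += X(row, l);
          double diff = csum[l] / (j + 1) - X(i, l);
          s += diff * diff;
        }
        dloc[j] = std::sqrt(s);
      }
      double acc_pn = 0.0, acc_lp = 0.0;
      for (int k = 0; k < k_max; ++k) {
        int j = std::min(k, kk - 1);
        if (k < kk) {
          acc_pn += ds[j] / (j + 1);
          acc_lp += dloc[j] / (j + 1);
        }
        if (dloc[j] < best_lm[k]) { best_lm[k] = dloc[j]; arg_lm[k] = c; }
        if (acc_pn < best_pn[k])  { best_pn[k] = acc_pn;  arg_pn[k] = c; }
        if (acc_lp < best_lp[k])  { best_lp[k] = acc_lp;  arg_lp[k] = c; }
      }
    }
    for (int k = 0; k < k_max; ++k) {
      out[i + (size_t)n * k] = arg_lm[k];
      out[i + (size_t)n * k + (size_t)n * k_max] = arg_pn[k];
      out[i + (size_t)n * k + 2 * (size_t)n * k_max] = arg_lp[k];
    }
  }
  out.attr("dim") = IntegerVector::create(n, k_max, 3);
  return out;
}
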