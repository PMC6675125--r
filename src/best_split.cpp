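#include <Rcpp.h>
#include <algorithm>
#include <numeric>

using namespace Rcpp;

// Exact squared-error-minimizing binary split. Candidate thresholds are the
// midpoints between consecutive distinct sorted values of each feature; ties
// across (feature, threshold) break to the smallest feature index, then the
// smallest threshold. Returns NULL when no candidate strictly reduces loss.
// [[Rcpp::export(name = ".best_split_cpp")]]
SEXP best_split_cpp(NumericMatrix X, NumericVector y,
                    double min_impurity_decrease) {
  const int n = y.size();
  const int d = X.ncol();
  double tot = 0.0, tot2 = 0.0;
  for (int i = 0; i < n; ++i) { tot += y[i]; tot2 += y[i] * y[i]; }
  const double parent_loss = tot2 - tot * tot / n;

  int best_j = -1;
  double best_s = 0.0, best_loss = 0.0;
  std::vector<int> ord(n);
  std::vector<double> xs(n), ys(n);

  for (int j = 0; j < d; ++j) {
    NumericMatrix::Column col = X(_, j);
    std::iota(ord.begin(), ord.end(), 0);
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return col[a] < col[b]; });
    for (int i = 0; i < n; ++i) { xs[i] = col[ord[i]]; ys[i] = y[ord[i]]; }
    double cs = 0.0, cs2 = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      cs += ys[i]; cs2 += ys[i] * ys[i];
      if (xs[i + 1] <= xs[i]) continue;
      const int nl = i + 1, nr = n - nl;
      const double loss = (cs2 - cs * cs / nl) +
                          ((tot2 - cs2) - (tot - cs) * (tot - cs) / nr);
      if (best_j < 0 || loss < best_loss) {
        best_j = j;
        best_s = (xs[i] + xs[i + 1]) / 2.0;
        best_loss = loss;
      }
    }
  }
  if (best_j < 0) return R_NilValue;
  const double decrease = parent_loss - best_loss;
  const double eps = 1e-12 * std::max(1.0, std::fabs(parent_loss));
  if (decrease <= eps || decrease < min_impurity_decrease) return R_NilValue;
  return List::create(_["j"] = best_j + 1, _["s"] = best_s,
                      _["loss"] = best_loss, _["decrease"] = decrease);
}
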