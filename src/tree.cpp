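#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exhaustive CART split search for one node: scans every feature and every
// midpoint between consecutive distinct sorted values, maximising the
// squared-error reduction  sumL^2/nL + sumR^2/nR - sumT^2/nT.
// Ties are broken toward the lowest feature index, then the lowest
// threshold, by strict-improvement updates while scanning in that order —
// this makes training fully deterministic.
//
// idx holds 1-based row indices of the samples reaching the node.
// Returns found=false when no split satisfies min_leaf on both sides or
// no positive gain exists.
// [[Rcpp::export]]
List best_split_cpp(NumericMatrix X, NumericVector y, IntegerVector idx,
                    int min_leaf) {
  const int n = idx.size();
  const int p = X.ncol();
  bool found = false;
  int best_feature = -1;
  double best_threshold = 0.0, best_gain = 0.0;

  double sum_t = 0.0;
  for (int k = 0; k < n; ++k) sum_t += y[idx[k] - 1];
  const double parent_score = sum_t * sum_t / n;

  std::vector<std::pair<double, double> > xy(n);
  for (int j = 0; j < p; ++j) {
    for (int k = 0; k < n; ++k) {
      const int row = idx[k] - 1;
      xy[k].first = X(row, j);
      xy[k].second = y[row];
    }
    std::sort(xy.begin(), xy.end());
    if (xy[0].first == xy[n - 1].first) continue; // constant feature

    double sum_l = 0.0;
    for (int k = 0; k < n - 1; ++k) {
      sum_l += xy[k].second;
      if (xy[k].first == xy[k + 1].first) continue; // not a boundary
      const int nl = k + 1, nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      const double sum_r = sum_t - sum_l;
      const double gain =
          sum_l * sum_l / nl + sum_r * sum_r / nr - parent_score;
      if (gain > best_gain) { // strict: first (lowest j, lowest thr) wins ties
        best_gain = gain;
        best_feature = j + 1;
        best_threshold = 0.5 * (xy[k].first + xy[k + 1].first);
        found = true;
      }
    }
  }

  return List::create(_["found"] = found, _["feature"] = best_feature,
                      _["threshold"] = best_threshold, _["gain"] = best_gain);
}
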