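#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Fill missing entries of a cells x bins matrix by distance-weighted
// k-nearest-neighbour imputation. `dist` is the full cell-cell distance
// matrix (missing-aware, already rescaled); non-finite distances mark
// cell pairs with no usable overlap. For each missing (i, j) the k nearest
// cells *with an observed value at j* contribute their value with weight
// 1 / distance; a zero-distance neighbour's value is used directly. Ties
// in distance break by cell order.
// [[Rcpp::export(name = ".knn_impute_fill")]]
List knn_impute_fill(NumericMatrix values, NumericMatrix dist, int k) {
  int n = values.nrow(), p = values.ncol();
  NumericMatrix out = clone(values);
  std::vector<int> obs;
  std::vector<std::pair<double, int> > cand;
  int n_short = 0;     // imputations with fewer than k usable neighbours
  int n_unfilled = 0;  // missing entries left unfilled (no neighbours)
  for (int j = 0; j < p; ++j) {
    obs.clear();
    for (int i = 0; i < n; ++i) {
      if (!NumericMatrix::is_na(values(i, j))) obs.push_back(i);
    }
    if (obs.empty()) {
      for (int i = 0; i < n; ++i) {
        if (NumericMatrix::is_na(values(i, j))) ++n_unfilled;
      }
      continue;  // bin missing in all cells: skip, reported by wrapper
    }
    for (int i = 0; i < n; ++i) {
      if (!NumericMatrix::is_na(values(i, j))) continue;
      cand.clear();
      for (size_t r = 0; r < obs.size(); ++r) {
        double d = dist(i, obs[r]);
        if (R_finite(d)) cand.push_back(std::make_pair(d, obs[r]));
      }
      if (cand.empty()) { ++n_unfilled; continue; }
      int use = std::min<int>(k, cand.size());
      if ((int)cand.size() < k) ++n_short;
      std::partial_sort(cand.begin(), cand.begin() + use, cand.end());
      if (cand[0].first <= 0.0) {
        out(i, j) = values(cand[0].second, j);  // exact profile match
        continue;
      }
      double num = 0.0, den = 0.0;
      for (int r = 0; r < use; ++r) {
        double w = 1.0 / cand[r].first;
        num += w * values(cand[r].second, j);
        den += w;
      }
      out(i, j) = num / den;
    }
  }
  return List::create(_["matrix"] = out, _["n_short"] = n_short,
                      _["n_unfilled"] = n_unfilled);
}
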