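#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static inline double h2(double pos, double tot) {
  if (tot <= 0.0) return 0.0;
  double p = pos / tot;
  if (p <= 0.0 || p >= 1.0) return 0.0;
  double q = 1.0 - p;
  return -(p * std::log2(p) + q * std::log2(q));
}

// Best gain-ratio split over all features for a binary target.
// Two-pass per feature: first find the max gain (for the C4.5 average-gain
// eligibility guard we track all candidate gains), then pick the split
// maximizing gain/split_info among those with >= mean gain.
// Returns (feature index 1-based, threshold, gain_ratio, gain) or feature 0
// if no valid split exists.
// [[Rcpp::export(name = ".best_split_cpp")]]
NumericVector best_split_cpp(NumericMatrix x, IntegerVector y01,
                             int min_leaf) {
  int n = x.nrow(), p = x.ncol();
  double total_pos = 0.0;
  for (int i = 0; i < n; ++i) total_pos += y01[i];
  double parent = h2(total_pos, n);

  std::vector<int> ord(n);
  std::vector<double> xs(n);
  std::vector<int> ys(n);
  std::vector<double> cand_gain, cand_si, cand_thr;

  double best_ratio = -1.0, best_thr = 0.0, best_gain = 0.0;
  int best_feat = 0;

  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) ord[i] = i;
    NumericMatrix::Column col = x(_, j);
    std::sort(ord.begin(), ord.end(),
              [&](int a, int b) { return col[a] < col[b]; });
    for (int i = 0; i < n; ++i) {
      xs[i] = col[ord[i]];
      ys[i] = y01[ord[i]];
    }
    cand_gain.clear(); cand_si.clear(); cand_thr.clear();
    double cum_pos = 0.0;
    for (int i = 0; i < n - 1; ++i) {
      cum_pos += ys[i];
      int nl = i + 1, nr = n - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      if (!(xs[i] < xs[i + 1])) continue;
      double child = (nl * h2(cum_pos, nl) +
                      nr * h2(total_pos - cum_pos, nr)) / n;
      double frac = (double)nl / n;
      double si = -(frac * std::log2(frac) +
                    (1.0 - frac) * std::log2(1.0 - frac));
      cand_gain.push_back(parent - child);
      cand_si.push_back(si);
      cand_thr.push_back(0.5 * (xs[i] + xs[i + 1]));
    }
    if (cand_gain.empty()) continue;
    double mean_gain = 0.0;
    for (double g : cand_gain) mean_gain += g;
    mean_gain /= cand_gain.size();
    for (size_t c = 0; c < cand_gain.size(); ++c) {
      if (cand_gain[c] + 1e-12 < mean_gain || cand_si[c] <= 0.0) continue;
      double ratio = cand_gain[c] / cand_si[c];
      if (ratio > best_ratio) {
        best_ratio = ratio;
        best_thr = cand_thr[c];
        best_gain = cand_gain[c];
        best_feat = j + 1;
      }
    }
  }
  return NumericVector::create(best_feat, best_thr, best_ratio, best_gain);
}
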