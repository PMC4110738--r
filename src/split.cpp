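// Inner loop of the gain-ratio split search: scan all binary thresholds of
// one numeric attribute.  Ties keep the earliest (lowest-threshold)
// candidate; a split must leave min_leaf rows on each side and improve on
// the parent entropy.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double ent_term(double c, double n) {
  if (c <= 0) return 0.0;
  double p = c / n;
  return -p * std::log2(p);
}

// returns c(found, threshold, gain, ratio)
// [[Rcpp::export]]
NumericVector cpp_best_split(NumericVector x, IntegerVector y, int nclass,
                             int min_leaf) {
  int n = x.size();
  NumericVector res = NumericVector::create(0.0, 0.0, 0.0, 0.0);
  if (n < 2 * min_leaf) return res;
  std::vector<int> o(n);
  for (int i = 0; i < n; ++i) o[i] = i;
  std::stable_sort(o.begin(), o.end(),
                   [&](int a, int b) { return x[a] < x[b]; });
  std::vector<double> total(nclass, 0.0), left(nclass, 0.0);
  for (int i = 0; i < n; ++i) total[y[i] - 1] += 1.0;
  double h_parent = 0.0;
  for (int c = 0; c < nclass; ++c) h_parent += ent_term(total[c], n);
  double bestRatio = -1.0, bestGain = 0.0, bestThr = 0.0;
  bool found = false;
  for (int i = 0; i < n - 1; ++i) {
    left[y[o[i]] - 1] += 1.0;
    if (x[o[i]] >= x[o[i + 1]]) continue;   // not a boundary
    double nl = i + 1.0, nr = n - nl;
    if (nl < min_leaf || nr < min_leaf) continue;
    double hl = 0.0, hr = 0.0;
    for (int c = 0; c < nclass; ++c) {
      hl += ent_term(left[c], nl);
      hr += ent_term(total[c] - left[c], nr);
    }
    double gain = h_parent - (nl * hl + nr * hr) / n;
    if (gain <= 1e-9) continue;
    double pl = nl / n;
    double si = -(pl * std::log2(pl) + (1.0 - pl) * std::log2(1.0 - pl));
    double ratio = si > 0 ? gain / si : 0.0;
    if (ratio > bestRatio + 1e-12) {
      bestRatio = ratio; bestGain = gain; bestThr = x[o[i]];
      found = true;
    }
  }
  if (found) {
    res[0] = 1.0; res[1] = bestThr; res[2] = bestGain; res[3] = bestRatio;
  }
  return res;
}
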