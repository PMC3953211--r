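#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Max over arcs of the circularized two-sample mean-difference statistic.
// For a segment x[0..n-1] circularized, every arc/complement split is indexed
// by boundary pair (i, j), 0 <= i < j <= n, arc = x[i..j-1] (0-based).
// Z_ij = |mean(arc) - mean(rest)| / sqrt(1/k + 1/(n-k)), k = arc length.
// The probe variance is a common factor across all (i, j) and across
// permutations of the same segment, so it cancels in both the argmax and the
// permutation p-value and is omitted.
static double max_arc_stat(const std::vector<double>& x, int min_width,
                           int* bi, int* bj) {
  const int n = (int)x.size();
  std::vector<double> S(n + 1, 0.0);
  for (int t = 0; t < n; ++t) S[t + 1] = S[t] + x[t];
  const double total = S[n];
  double best = -1.0;
  int besti = 0, bestj = n;
  for (int k = min_width; k <= n - min_width; ++k) {
    const double denom = std::sqrt(1.0 / k + 1.0 / (n - k));
    for (int i = 0; i + k <= n; ++i) {
      const int j = i + k;
      const double arc = S[j] - S[i];
      const double m1 = arc / k;
      const double m2 = (total - arc) / (n - k);
      const double z = std::fabs(m1 - m2) / denom;
      if (z > best) { best = z; besti = i; bestj = j; }
    }
  }
  if (bi) *bi = besti;
  if (bj) *bj = bestj;
  return best;
}

// [[Rcpp::export(name = ".cbs_max_stat")]]
List cbs_max_stat(NumericVector x, int min_width) {
  const int n = x.size();
  if (n < 2 * min_width)
    return List::create(_["stat"] = 0.0, _["i"] = 0, _["j"] = n);
  std::vector<double> xv(x.begin(), x.end());
  int i, j;
  double s = max_arc_stat(xv, min_width, &i, &j);
  return List::create(_["stat"] = s, _["i"] = i, _["j"] = j);
}

// Permutation exceedance count for the arc-max statistic, with early exit
// once `max_exceed` exceedances are seen (at that point the split is already
// non-significant at the caller's alpha, so further permutations cannot
// change the decision). Uses R's RNG so results follow set.seed().
// [[Rcpp::export(name = ".cbs_perm_count")]]
List cbs_perm_count(NumericVector x, int min_width, int n_perm,
                    double observed, int max_exceed) {
  const int n = x.size();
  std::vector<double> xv(x.begin(), x.end());
  int count = 0, done = 0;
  for (int p = 0; p < n_perm; ++p) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int t = n - 1; t > 0; --t) {
      int u = (int)(unif_rand() * (t + 1));
      if (u > t) u = t;
      std::swap(xv[t], xv[u]);
    }
    double s = max_arc_stat(xv, min_width, nullptr, nullptr);
    if (s >= observed) ++count;
    ++done;
    if (count >= max_exceed) break;
  }
  return List::create(_["count"] = count, _["n_done"] = done);
}
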