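#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Optimal 1:1 caliper matching of two score-sorted lists.
//
// For costs |x_i - y_j| on a line, an optimal matching that (1) maximises
// the number of pairs admissible under the caliper and (2) minimises the
// total within-pair distance can always be taken non-crossing: uncrossing
// two crossing pairs never increases the total distance and never increases
// either pair's distance (so caliper feasibility is preserved). The
// non-crossing optimum is found by dynamic programming over the two sorted
// lists with a lexicographic (count desc, distance asc) objective.
//
// x, y must be sorted increasing. Returns, for each element of x, the
// 1-based index of its match in y, or 0 if unmatched.
// [[Rcpp::export]]
IntegerVector caliper_match_dp(NumericVector x, NumericVector y,
                               double caliper) {
  const int m = x.size(), n = y.size();
  const double cells = (double)(m + 1) * (double)(n + 1);
  if (cells > 4e8)
    stop("matching problem too large for the exact matcher (%d x %d)", m, n);

  std::vector<int> cnt((size_t)cells, 0);
  std::vector<double> dist((size_t)cells, 0.0);
  const size_t W = n + 1;
  auto better = [](int c1, double d1, int c2, double d2) {
    return c1 > c2 || (c1 == c2 && d1 < d2);
  };

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      // candidates: skip exposed i, skip control j, pair (i, j)
      int bc = cnt[(i - 1) * W + j];
      double bd = dist[(i - 1) * W + j];
      if (better(cnt[i * W + (j - 1)], dist[i * W + (j - 1)], bc, bd)) {
        bc = cnt[i * W + (j - 1)];
        bd = dist[i * W + (j - 1)];
      }
      double d = std::abs(x[i - 1] - y[j - 1]);
      if (d <= caliper) {
        int pc = cnt[(i - 1) * W + (j - 1)] + 1;
        double pd = dist[(i - 1) * W + (j - 1)] + d;
        if (better(pc, pd, bc, bd)) { bc = pc; bd = pd; }
      }
      cnt[i * W + j] = bc;
      dist[i * W + j] = bd;
    }
  }

  IntegerVector match(m, 0);
  int i = m, j = n;
  while (i > 0 && j > 0) {
    double d = std::abs(x[i - 1] - y[j - 1]);
    if (d <= caliper &&
        cnt[i * W + j] == cnt[(i - 1) * W + (j - 1)] + 1 &&
        dist[i * W + j] == dist[(i - 1) * W + (j - 1)] + d) {
      match[i - 1] = j;
      --i; --j;
    } else if (cnt[i * W + j] == cnt[i * W + (j - 1)] &&
               dist[i * W + j] == dist[i * W + (j - 1)]) {
      --j;
    } else {
      --i;
    }
  }
  return match;
}
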