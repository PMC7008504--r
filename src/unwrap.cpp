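#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Quality-guided flood-fill phase unwrapping. Starting from the
// highest-quality valid pixel (which keeps its wrapped value), pixels are
// absorbed in decreasing quality order; when a pixel is absorbed it is
// assigned wrapped + 2*pi*k with k chosen so it lies within pi of its
// best-quality already-solved 4-neighbor. Disconnected valid regions are
// unwrapped independently, each anchored at its own highest-quality pixel.
// [[Rcpp::export]]
NumericMatrix unwrap_phase_cpp(NumericMatrix wrapped, NumericMatrix quality,
                               LogicalMatrix valid) {
  const int nr = wrapped.nrow(), nc = wrapped.ncol();
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<char> solved(nr * nc, 0), queued(nr * nc, 0);

  typedef std::pair<double, int> Item; // (quality, pixel)
  std::priority_queue<Item> pq;
  const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
  const double TWO_PI = 2.0 * M_PI;

  // repeat until every valid pixel is solved (handles disconnected regions)
  for (;;) {
    int seed = -1; double best = -1.0;
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) {
        int p = i + j * nr;
        if (valid(i, j) && !solved[p] && quality(i, j) > best) {
          best = quality(i, j); seed = p;
        }
      }
    if (seed < 0) break;
    out[seed] = wrapped[seed];          // anchor keeps its wrapped value
    solved[seed] = 1; queued[seed] = 1;
    pq.push(Item(best, seed));

    while (!pq.empty()) {
      int p = pq.top().second; pq.pop();
      int i = p % nr, j = p / nr;
      if (!solved[p]) {
        // unwrap from the best-quality solved neighbor
        int from = -1; double qbest = -1.0;
        for (int k = 0; k < 4; ++k) {
          int ii = i + dr[k], jj = j + dc[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          int pn = ii + jj * nr;
          if (solved[pn] && quality(ii, jj) > qbest) { qbest = quality(ii, jj); from = pn; }
        }
        if (from < 0) continue;          // unreachable; re-seeded later
        double kk = std::floor((out[from] - wrapped[p]) / TWO_PI + 0.5);
        out[p] = wrapped[p] + TWO_PI * kk;
        solved[p] = 1;
      }
      for (int k = 0; k < 4; ++k) {
        int ii = i + dr[k], jj = j + dc[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        int pn = ii + jj * nr;
        if (valid(ii, jj) && !queued[pn]) {
          queued[pn] = 1;
          pq.push(Item(quality(ii, jj), pn));
        }
      }
    }
  }
  return out;
}
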