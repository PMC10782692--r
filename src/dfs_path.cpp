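#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Exhaustive depth-first search with backtracking for the maximum-count
// simple path of L edge-adjacent (4-neighborhood) eligible cells.
//
// Pruning is admissible only: a branch is cut when its current sum plus the
// sum of the L-depth largest eligible cell counts anywhere on the grid cannot
// beat the incumbent. Start cells are ordered by descending total count in
// their Manhattan-(L-1) neighborhood (ties row-major) so a strong incumbent
// is found early; incumbent updates are strict, so the first optimum found
// under the deterministic N,E,S,W neighbor order is returned.

namespace {

struct Search {
  int nr, nc, L;
  const int *cnt;          // column-major, as stored by R
  std::vector<char> elig;
  std::vector<char> visited;
  std::vector<long long> topsum;  // topsum[m] = sum of m largest eligible counts
  long long best;
  bool found;
  std::vector<int> cur, bestPath;

  int at(int r, int c) const { return r + nr * c; }

  void dfs(int r, int c, int depth, long long sum) {
    int idx = at(r, c);
    cur[depth - 1] = idx;
    if (depth == L) {
      if (!found || sum > best) {
        best = sum;
        bestPath = cur;
        found = true;
      }
      return;
    }
    if (found && sum + topsum[L - depth] <= best) return;
    static const int dr[4] = {-1, 0, 1, 0};  // N, E, S, W
    static const int dc[4] = {0, 1, 0, -1};
    for (int k = 0; k < 4; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      int j = at(r2, c2);
      if (!elig[j] || visited[j]) continue;
      visited[j] = 1;
      dfs(r2, c2, depth + 1, sum + cnt[j]);
      visited[j] = 0;
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".dfs_max_path_cpp")]]
List dfs_max_path_cpp(IntegerMatrix counts, LogicalMatrix eligible, int L) {
  Search s;
  s.nr = counts.nrow();
  s.nc = counts.ncol();
  s.L = L;
  s.cnt = counts.begin();
  s.elig.assign(s.nr * s.nc, 0);
  s.visited.assign(s.nr * s.nc, 0);
  std::vector<long long> eligCounts;
  for (int j = 0; j < s.nr * s.nc; ++j) {
    if (eligible[j]) {
      s.elig[j] = 1;
      eligCounts.push_back(counts[j]);
    }
  }
  if ((int)eligCounts.size() < L) {
    return List::create(_["found"] = false);
  }
  std::sort(eligCounts.begin(), eligCounts.end(), std::greater<long long>());
  s.topsum.assign(L + 1, 0);
  for (int m = 1; m <= L; ++m) s.topsum[m] = s.topsum[m - 1] + eligCounts[m - 1];

  // start order: descending count mass within Manhattan radius L-1, ties row-major
  std::vector<std::pair<long long, int> > starts;  // (-mass, row-major rank)
  std::vector<int> startIdx;
  for (int r = 0; r < s.nr; ++r) {
    for (int c = 0; c < s.nc; ++c) {
      if (!s.elig[s.at(r, c)]) continue;
      long long mass = 0;
      int R = L - 1;
      for (int r2 = std::max(0, r - R); r2 <= std::min(s.nr - 1, r + R); ++r2) {
        int rem = R - std::abs(r2 - r);
        for (int c2 = std::max(0, c - rem); c2 <= std::min(s.nc - 1, c + rem); ++c2) {
          if (s.elig[s.at(r2, c2)]) mass += counts(r2, c2);
        }
      }
      starts.push_back(std::make_pair(-mass, r * s.nc + c));
      startIdx.push_back(s.at(r, c));
    }
  }
  std::vector<int> order(starts.size());
  for (size_t i = 0; i < order.size(); ++i) order[i] = (int)i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    return starts[a] < starts[b];
  });

  s.best = -1;
  s.found = false;
  s.cur.assign(L, -1);
  for (size_t oi = 0; oi < order.size(); ++oi) {
    int idx = startIdx[order[oi]];
    int r = idx % s.nr, c = idx / s.nr;
    if (s.found && (long long)counts[idx] + s.topsum[L - 1] <= s.best) continue;
    s.visited[idx] = 1;
    s.dfs(r, c, 1, counts[idx]);
    s.visited[idx] = 0;
  }
  if (!s.found) {
    return List::create(_["found"] = false);
  }
  IntegerMatrix path(L, 2);
  for (int i = 0; i < L; ++i) {
    path(i, 0) = s.bestPath[i] % s.nr + 1;  // matrix row, 1-based
    path(i, 1) = s.bestPath[i] / s.nr + 1;
  }
  return List::create(_["found"] = true,
                      _["count"] = (double)s.best,
                      _["path"] = path);
}
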