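#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Lance-Williams agglomeration over a full dissimilarity matrix.
// linkage codes: 0 = single, 1 = complete, 2 = average, 3 = ward.
// For Ward the caller passes *squared* Euclidean distances (ward.D2
// dialect) or raw distances (ward.D); the recurrence coefficients are
// identical, only the input scale differs.
//
// Ties at the minimum are broken by the lexicographically smallest
// (slot_i, slot_j) pair of original matrix positions; the merged
// cluster stays in the lower slot so the active list remains sorted.
// A per-row nearest-neighbour cache (over higher slots only) avoids
// rescanning all pairs at every step; rows whose cached neighbour was
// touched by the merge are rescanned, which keeps the tie-break
// behaviour identical to the naive full scan.
// [[Rcpp::export]]
List agglomerate_cpp(NumericMatrix dist, int linkage) {
  const int n = dist.nrow();
  if (n < 2) stop("need at least two observations");
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> D(dist.begin(), dist.end());  // column-major
  std::vector<int> act(n);
  for (int i = 0; i < n; i++) act[i] = i;
  std::vector<double> size(n, 1.0);
  std::vector<int> id(n);
  for (int i = 0; i < n; i++) id[i] = -(i + 1);
  std::vector<int> nn(n, -1);
  std::vector<double> nnd(n, INF);
  std::vector<int> pos(n);  // position of slot in act

  IntegerMatrix merge(n - 1, 2);
  NumericVector height(n - 1);

  // rescan nearest neighbour of slot i over active slots after it
  auto rescan = [&](size_t a) {
    int i = act[a];
    double best = INF;
    int bj = -1;
    for (size_t b = a + 1; b < act.size(); b++) {
      int j = act[b];
      double d = D[i + (size_t)n * j];
      if (d < best) { best = d; bj = j; }
    }
    nnd[i] = best;
    nn[i] = bj;
  };

  for (size_t a = 0; a + 1 < act.size(); a++) rescan(a);
  if (!act.empty()) { nnd[act.back()] = INF; nn[act.back()] = -1; }

  for (int m = 0; m < n - 1; m++) {
    // global minimum over cached row minima; ascending slot scan with
    // strict < reproduces the lexicographic tie rule
    double best = INF;
    int bi = -1, bj = -1;
    for (size_t a = 0; a + 1 < act.size(); a++) {
      int i = act[a];
      if (nnd[i] < best) { best = nnd[i]; bi = i; bj = nn[i]; }
    }
    // Lance-Williams update of distances to the merged cluster
    for (size_t a = 0; a < act.size(); a++) {
      int k = act[a];
      if (k == bi || k == bj) continue;
      double dik = D[bi + (size_t)n * k];
      double djk = D[bj + (size_t)n * k];
      double nd;
      if (linkage == 0) {
        nd = dik < djk ? dik : djk;
      } else if (linkage == 1) {
        nd = dik > djk ? dik : djk;
      } else if (linkage == 2) {
        nd = (size[bi] * dik + size[bj] * djk) / (size[bi] + size[bj]);
      } else {
        double ni = size[bi], nj = size[bj], nk = size[k];
        nd = ((ni + nk) * dik + (nj + nk) * djk - nk * best) /
             (ni + nj + nk);
      }
      D[bi + (size_t)n * k] = nd;
      D[k + (size_t)n * bi] = nd;
    }
    merge(m, 0) = id[bi];
    merge(m, 1) = id[bj];
    height[m] = best;
    size[bi] += size[bj];
    id[bi] = m + 1;

    // drop bj from the active list
    for (size_t a = 0; a < act.size(); a++) pos[act[a]] = (int)a;
    act.erase(act.begin() + pos[bj]);
    for (size_t a = 0; a < act.size(); a++) pos[act[a]] = (int)a;

    // refresh caches: rows pointing at bi or bj, row bi itself, and
    // rows before bi whose distance to bi changed
    size_t na = act.size();
    for (size_t a = 0; a + 1 < na; a++) {
      int i = act[a];
      if (i == bi || nn[i] == bi || nn[i] == bj) {
        rescan(a);
      } else if (i < bi) {
        double d = D[i + (size_t)n * bi];
        if (d < nnd[i] || (d == nnd[i] && bi < nn[i])) {
          nnd[i] = d;
          nn[i] = bi;
        }
      }
    }
    if (!act.empty()) { nnd[act.back()] = INF; nn[act.back()] = -1; }
  }
  return List::create(_["merge"] = merge, _["height"] = height);
}
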