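#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <unordered_map>
using namespace Rcpp;

// Agglomerative clustering under complete linkage on a precomputed distance
// matrix. Ties are broken deterministically: among all pairs attaining the
// minimal inter-cluster distance, the pair (i, j), i < j, with the smallest i
// and then the smallest j is merged, where i, j index clusters in order of
// creation (leaves first, in input order, then internal nodes).
//
// Returns merge (n-1 x 2, stats::hclust convention: negative = leaf index,
// positive = earlier merge row) and height.
// [[Rcpp::export(name = ".agglomerate_complete")]]
List agglomerate_complete(NumericMatrix d) {
  const int n = d.nrow();
  if (n < 2) stop("need at least two items to cluster");
  // active clusters carry an hclust id (negative leaf or positive merge row)
  std::vector<int> id(n);
  std::vector<bool> alive(n, true);
  for (int i = 0; i < n; ++i) id[i] = -(i + 1);
  NumericMatrix D = clone(d);
  IntegerMatrix merge(n - 1, 2);
  NumericVector height(n - 1);

  for (int step = 0; step < n - 1; ++step) {
    double best = R_PosInf;
    int bi = -1, bj = -1;
    for (int i = 0; i < n; ++i) {
      if (!alive[i]) continue;
      for (int j = i + 1; j < n; ++j) {
        if (!alive[j]) continue;
        if (D(i, j) < best) { best = D(i, j); bi = i; bj = j; }
      }
    }
    int a = id[bi], b = id[bj];
    // hclust convention: singletons (by input index) before clusters,
    // both ascending within their kind
    if ((a < 0 && b < 0 && a < b) || (a > 0 && b > 0 && a > b) ||
        (a > 0 && b < 0)) std::swap(a, b);
    merge(step, 0) = a;
    merge(step, 1) = b;
    height[step] = best;
    // complete linkage: D(new, k) = max(D(i,k), D(j,k)); new cluster kept in
    // slot bi (the smaller slot), so creation order is preserved by slot order
    for (int k = 0; k < n; ++k) {
      if (!alive[k] || k == bi || k == bj) continue;
      double m = std::max(D(bi, k), D(bj, k));
      D(bi, k) = m; D(k, bi) = m;
    }
    alive[bj] = false;
    id[bi] = step + 1;
  }
  return List::create(_["merge"] = merge, _["height"] = height);
}

// Connected-component labelling of a binary matrix with 4- or 8-connectivity.
// Labels are assigned in column-major scan order starting at 1.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(IntegerMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  const int dr4[] = {-1, 1, 0, 0}, dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *dr = connectivity == 4 ? dr4 : dr8;
  const int *dc = connectivity == 4 ? dc4 : dc8;
  const int nd = connectivity;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int k = 0; k < nd; ++k) {
          int qr = pr + dr[k], qc = pc + dc[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (mask(qr, qc) != 0 && lab(qr, qc) == 0) {
            lab(qr, qc) = next;
            stack.push_back(qr + qc * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Bootstrap cluster-recovery counts for one resampling scale.
// m: items x variables data matrix; idx: n' x n_boot matrix of 1-based
// column indices (drawn in R so the RNG stream is owned by the caller);
// targets: list of integer vectors of 1-based leaf indices (the reference
// tree's clusters). Requires <= 64 items; agglomeration is complete-linkage
// on squared Euclidean distances (same merge order, heights unused) with the
// same deterministic tie-breaking as .agglomerate_complete.
// [[Rcpp::export(name = ".bootstrap_hits")]]
IntegerVector bootstrap_hits(NumericMatrix m, IntegerMatrix idx,
                             List targets) {
  const int n = m.nrow();
  if (n > 64) stop("fast bootstrap path supports at most 64 items");
  const int nboot = idx.ncol(), np = idx.nrow(), nt = targets.size();
  std::vector<uint64_t> tmask(nt);
  std::unordered_map<uint64_t, int> lookup;
  for (int t = 0; t < nt; ++t) {
    IntegerVector leaves = targets[t];
    uint64_t msk = 0;
    for (int l = 0; l < leaves.size(); ++l)
      msk |= (uint64_t(1) << (leaves[l] - 1));
    tmask[t] = msk;
    lookup[msk] = t;
  }
  IntegerVector counts(nt);
  std::vector<double> D(n * n);
  std::vector<uint64_t> mask(n);
  std::vector<bool> alive(n);
  std::vector<bool> seen(nt);
  for (int b = 0; b < nboot; ++b) {
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double s = 0;
        for (int c = 0; c < np; ++c) {
          int col = idx(c, b) - 1;
          double d = m(i, col) - m(j, col);
          s += d * d;
        }
        D[i * n + j] = s; D[j * n + i] = s;
      }
      mask[i] = uint64_t(1) << i;
      alive[i] = true;
    }
    std::fill(seen.begin(), seen.end(), false);
    for (int step = 0; step < n - 1; ++step) {
      double best = R_PosInf;
      int bi = -1, bj = -1;
      for (int i = 0; i < n; ++i) {
        if (!alive[i]) continue;
        for (int j = i + 1; j < n; ++j) {
          if (!alive[j]) continue;
          if (D[i * n + j] < best) { best = D[i * n + j]; bi = i; bj = j; }
        }
      }
      for (int k = 0; k < n; ++k) {
        if (!alive[k] || k == bi || k == bj) continue;
        double mx = std::max(D[bi * n + k], D[bj * n + k]);
        D[bi * n + k] = mx; D[k * n + bi] = mx;
      }
      alive[bj] = false;
      mask[bi] |= mask[bj];
      auto hit = lookup.find(mask[bi]);
      if (hit != lookup.end() && !seen[hit->second]) {
        seen[hit->second] = true;
        ++counts[hit->second];
      }
    }
  }
  return counts;
}
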