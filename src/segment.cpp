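#include <Rcpp.h>
#include <queue>
#include <vector>
#include <set>
#include <cmath>
using namespace Rcpp;

// 8-connected component labelling of equal-valued cells, skipping the
// background value. Labels are assigned in raster scan order (row-major
// over columns of the R matrix, i.e. column-major storage), so results
// are deterministic.
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(IntegerMatrix codes, int background) {
  int nr = codes.nrow(), nc = codes.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> stack;
  const int dr[8] = {-1,-1,-1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1,-1, 1,-1, 0, 1};
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (codes(r, c) == background || lab(r, c) != 0) continue;
      int val = codes(r, c);
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int k = 0; k < 8; ++k) {
          int qr = pr + dr[k], qc = pc + dc[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (lab(qr, qc) == 0 && codes(qr, qc) == val) {
            lab(qr, qc) = next;
            stack.push_back(qr + qc * nr);
          }
        }
      }
    }
  }
  return lab;
}

struct Edge {
  double d;
  int a, b;  // root ids, a < b
  bool operator>(const Edge& o) const {
    if (d != o.d) return d > o.d;
    if (a != o.a) return a > o.a;
    return b > o.b;
  }
};

class UF {
public:
  std::vector<int> parent;
  UF(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
};

static double seg_dist(const std::vector<double>& sum, const std::vector<int>& size,
                       int a, int b, int nb) {
  double s = 0.0;
  for (int j = 0; j < nb; ++j) {
    double ma = sum[(size_t)a * nb + j] / size[a];
    double mb = sum[(size_t)b * nb + j] / size[b];
    s += (ma - mb) * (ma - mb);
  }
  return std::sqrt(s);
}

// Best-merge region-growing segmentation with MMU enforcement.
// features: n_valid x n_bands matrix, rows aligned with which(valid) in
// column-major order. valid: logical matrix. Returns an integer matrix of
// contiguous segment ids (1..n) over valid pixels, 0 elsewhere.
// [[Rcpp::export(name = ".segment_cpp")]]
IntegerMatrix segment_cpp(NumericMatrix features, LogicalMatrix valid,
                          double merge_threshold, int mmu) {
  int nr = valid.nrow(), nc = valid.ncol();
  int nb = features.ncol();
  // map pixel -> node index
  std::vector<int> node(nr * (size_t)nc, -1);
  int n = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (valid(r, c)) node[r + (size_t)c * nr] = n++;
  IntegerMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), 0);
  if (n == 0) return out;
  if ((int)features.nrow() != n) stop("feature rows must equal valid pixel count");

  std::vector<double> sum((size_t)n * nb);
  std::vector<int> size(n, 1);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < nb; ++j)
      sum[(size_t)i * nb + j] = features(i, j);

  UF uf(n);
  // adjacency sets over roots
  std::vector< std::set<int> > adj(n);
  const int dr[8] = {-1,-1,-1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1,-1, 1,-1, 0, 1};
  std::priority_queue<Edge, std::vector<Edge>, std::greater<Edge> > heap;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int i = node[r + (size_t)c * nr];
      if (i < 0) continue;
      for (int k = 0; k < 8; ++k) {
        int qr = r + dr[k], qc = c + dc[k];
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        int j = node[qr + (size_t)qc * nr];
        if (j < 0 || j <= i) continue;
        adj[i].insert(j);
        adj[j].insert(i);
        double d = seg_dist(sum, size, i, j, nb);
        if (d < merge_threshold) heap.push(Edge{d, i, j});
      }
    }
  }

  auto do_merge = [&](int a, int b) {
    // merge root b into root a (keep smaller id as root for determinism)
    if (a > b) std::swap(a, b);
    uf.parent[b] = a;
    for (int j = 0; j < nb; ++j) sum[(size_t)a * nb + j] += sum[(size_t)b * nb + j];
    size[a] += size[b];
    for (int x : adj[b]) {
      int rx = uf.find(x);
      if (rx == a) continue;
      adj[a].insert(rx);
      adj[rx].erase(b);
      adj[rx].insert(a);
    }
    adj[b].clear();
    return a;
  };

  while (!heap.empty()) {
    Edge e = heap.top(); heap.pop();
    int ra = uf.find(e.a), rb = uf.find(e.b);
    if (ra == rb) continue;
    if (ra != e.a || rb != e.b) continue;  // stale roots
    // both endpoints still roots => still adjacent (merging only grows
    // adjacency), so no explicit adjacency check is needed
    double d = seg_dist(sum, size, ra, rb, nb);
    if (d > e.d + 1e-12) {  // means drifted since push; re-queue if viable
      if (d < merge_threshold) {
        int a = std::min(ra, rb), b = std::max(ra, rb);
        heap.push(Edge{d, a, b});
      }
      continue;
    }
    if (d >= merge_threshold) continue;
    int root = do_merge(ra, rb);
    // refresh candidate edges from the merged segment
    for (int x : adj[root]) {
      int rx = uf.find(x);
      if (rx == root) continue;
      double dn = seg_dist(sum, size, root, rx, nb);
      if (dn < merge_threshold) {
        int a = std::min(root, rx), b = std::max(root, rx);
        heap.push(Edge{dn, a, b});
      }
    }
  }

  // MMU pass: repeatedly merge the smallest undersized segment into its
  // spectrally nearest adjacent segment (ties -> smallest root id).
  // Undersized segments with no neighbour at all (isolated valid
  // components below the MMU) are dropped from the segment map.
  std::vector<bool> dropped(n, false);
  bool changed = true;
  while (changed) {
    changed = false;
    int pick = -1;
    for (int i = 0; i < n; ++i) {
      if (uf.find(i) != i) continue;
      if (size[i] >= mmu) continue;
      if (pick < 0 || size[i] < size[pick] ||
          (size[i] == size[pick] && i < pick)) pick = i;
    }
    if (pick >= 0) {
      double best = R_PosInf; int bestj = -1;
      for (int x : adj[pick]) {
        int rx = uf.find(x);
        if (rx == pick) continue;
        double d = seg_dist(sum, size, pick, rx, nb);
        if (d < best || (d == best && rx < bestj)) { best = d; bestj = rx; }
      }
      if (bestj >= 0) { do_merge(pick, bestj); changed = true; }
      else {
        dropped[pick] = true;
        size[pick] = mmu;  // terminate the loop for this root
        changed = true;
      }
    }
  }

  // contiguous ids in scan order
  std::vector<int> remap(n, 0);
  int next_id = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int i = node[r + (size_t)c * nr];
      if (i < 0) continue;
      int root = uf.find(i);
      if (dropped[root]) continue;
      if (remap[root] == 0) remap[root] = ++next_id;
      out(r, c) = remap[root];
    }
  }
  return out;
}
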