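#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// Union-find with path compression
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Partition single-layer pixel hits into clusters: two hits are linked when
// their pixels are adjacent (8- or 4-connected, or the same pixel) AND their
// times of arrival differ by at most time_window. Returns a 1-based cluster
// id per hit; ids are renumbered by order of first appearance so that the
// labelling is independent of any internal ordering.
// [[Rcpp::export]]
IntegerVector cluster_hits_cpp(IntegerVector col, IntegerVector row,
                               NumericVector toa, double time_window,
                               bool eight_connected) {
  const int n = col.size();
  IntegerVector out(n);
  if (n == 0) return out;
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;

  // hash pixel -> indices of hits on that pixel
  std::unordered_map<long long, std::vector<int> > grid;
  grid.reserve(n * 2);
  const long long K = 1LL << 20;  // pixel key stride (columns < 2^20)
  for (int i = 0; i < n; ++i) grid[(long long)col[i] * K + row[i]].push_back(i);

  const int dc8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dr8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dc4[4] = {-1, 1, 0, 0};
  const int dr4[4] = {0, 0, -1, 1};
  const int nd = eight_connected ? 8 : 4;
  const int* dc = eight_connected ? dc8 : dc4;
  const int* dr = eight_connected ? dr8 : dr4;

  for (int i = 0; i < n; ++i) {
    long long key = (long long)col[i] * K + row[i];
    // same pixel (repeated firings) counts as adjacent
    const std::vector<int>& same = grid[key];
    for (size_t k = 0; k < same.size(); ++k) {
      int j = same[k];
      if (j > i && std::abs(toa[i] - toa[j]) <= time_window)
        uf_union(parent, i, j);
    }
    for (int a = 0; a < nd; ++a) {
      long long nkey = (long long)(col[i] + dc[a]) * K + (row[i] + dr[a]);
      std::unordered_map<long long, std::vector<int> >::iterator it =
        grid.find(nkey);
      if (it == grid.end()) continue;
      const std::vector<int>& nb = it->second;
      for (size_t k = 0; k < nb.size(); ++k) {
        int j = nb[k];
        if (j > i && std::abs(toa[i] - toa[j]) <= time_window)
          uf_union(parent, i, j);
      }
    }
  }

  std::unordered_map<int, int> relabel;
  relabel.reserve(n);
  int next_id = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf_find(parent, i);
    std::unordered_map<int, int>::iterator it = relabel.find(r);
    if (it == relabel.end()) {
      relabel[r] = ++next_id;
      out[i] = next_id;
    } else {
      out[i] = it->second;
    }
  }
  return out;
}

// Greedy coincidence matching of front- and back-layer cluster timestamps.
// Candidate pairs are all (front, back) with |dt| <= window; they are taken
// in order of increasing |dt|, ties broken by earlier front time then
// earlier back time, skipping pairs whose front or back cluster is already
// matched. Inputs need not be sorted. Returns a two-column matrix of 1-based
// (front, back) indices into the input vectors.
// [[Rcpp::export]]
IntegerMatrix greedy_match_cpp(NumericVector ft, NumericVector bt,
                               double window) {
  const int nf = ft.size(), nb = bt.size();
  if (nf == 0 || nb == 0) return IntegerMatrix(0, 2);

  std::vector<int> fo(nf), bo(nb);
  for (int i = 0; i < nf; ++i) fo[i] = i;
  for (int i = 0; i < nb; ++i) bo[i] = i;
  std::sort(fo.begin(), fo.end(),
            [&](int a, int b) { return ft[a] < ft[b]; });
  std::sort(bo.begin(), bo.end(),
            [&](int a, int b) { return bt[a] < bt[b]; });

  struct Cand { double adt, f_t, b_t; int fi, bi; };
  std::vector<Cand> cands;
  int lo = 0;
  for (int a = 0; a < nf; ++a) {
    double t = ft[fo[a]];
    while (lo < nb && bt[bo[lo]] < t - window) ++lo;
    for (int b = lo; b < nb && bt[bo[b]] <= t + window; ++b) {
      Cand c;
      c.adt = std::abs(t - bt[bo[b]]);
      c.f_t = t; c.b_t = bt[bo[b]];
      c.fi = fo[a]; c.bi = bo[b];
      cands.push_back(c);
    }
  }
  std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
    if (a.adt != b.adt) return a.adt < b.adt;
    if (a.f_t != b.f_t) return a.f_t < b.f_t;
    if (a.b_t != b.b_t) return a.b_t < b.b_t;
    if (a.fi != b.fi) return a.fi < b.fi;
    return a.bi < b.bi;
  });

  std::vector<char> fused(nf, 0), bused(nb, 0);
  std::vector<int> mf, mb;
  for (size_t k = 0; k < cands.size(); ++k) {
    const Cand& c = cands[k];
    if (fused[c.fi] || bused[c.bi]) continue;
    fused[c.fi] = 1; bused[c.bi] = 1;
    mf.push_back(c.fi + 1); mb.push_back(c.bi + 1);
  }
  IntegerMatrix out(mf.size(), 2);
  for (size_t k = 0; k < mf.size(); ++k) {
    out(k, 0) = mf[k];
    out(k, 1) = mb[k];
  }
  return out;
}
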