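#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path halving.
static inline int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static inline void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra < rb) parent[rb] = ra; else if (rb < ra) parent[ra] = rb;
}

//' Connected-component labeling of a binary mask
//'
//' Two-pass union-find labeling. Components are numbered 1..n in
//' column-major scan order of their first pixel, so the result is fully
//' deterministic.
//'
//' @param mask logical matrix, TRUE = foreground.
//' @param connectivity 4 or 8 (8 merges diagonally touching pixels).
//' @return integer matrix of the same shape; 0 = background.
//' @keywords internal
// [[Rcpp::export]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity = 8) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.reserve(256);
  int next = 0;
  // first pass: column-major scan; neighbours already visited are
  // (r-1,c), (r,c-1) and for 8-connectivity (r-1,c-1), (r+1,c-1)
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int best = -1;
      int nb[4][2] = {{r - 1, c}, {r, c - 1}, {r - 1, c - 1}, {r + 1, c - 1}};
      int nn = (connectivity == 8) ? 4 : 2;
      for (int k = 0; k < nn; ++k) {
        int rr = nb[k][0], cc = nb[k][1];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        int l = lab(rr, cc);
        if (l > 0) {
          if (best < 0) best = l - 1;
          else uf_union(parent, best, l - 1);
        }
      }
      if (best < 0) {
        parent.push_back(next);
        best = next++;
      }
      lab(r, c) = best + 1;
    }
  }
  // resolve labels, renumber in scan order of first appearance
  std::vector<int> remap(next, 0);
  int count = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = uf_find(parent, l - 1);
      if (remap[root] == 0) remap[root] = ++count;
      lab(r, c) = remap[root];
    }
  }
  return lab;
}
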