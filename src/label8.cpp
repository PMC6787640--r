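#include <Rcpp.h>
using namespace Rcpp;

// 8-connected component labelling of a binary mask via two-pass
// union-find. Components are renumbered 1..k by the raster (row-major)
// position of each component's first pixel, so labels are deterministic
// for a given mask.
// [[Rcpp::export]]
IntegerMatrix cc_label_8(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);

  auto find = [&parent](int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  };

  int next = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c)) continue;
      // previously scanned 8-neighbours in row-major order
      const int nb[4][2] = {{r - 1, c - 1}, {r - 1, c}, {r - 1, c + 1}, {r, c - 1}};
      int best = 0;
      for (int k = 0; k < 4; ++k) {
        const int rr = nb[k][0], cc = nb[k][1];
        if (rr < 0 || cc < 0 || cc >= nc) continue;
        const int l = lab(rr, cc);
        if (l == 0) continue;
        const int root = find(l);
        if (best == 0) {
          best = root;
        } else if (root != best) {
          const int a = std::min(best, root), b = std::max(best, root);
          parent[b] = a;
          best = a;
        }
      }
      if (best == 0) {
        parent.push_back(++next);
        best = next;
      }
      lab(r, c) = best;
    }
  }

  std::vector<int> newid(next + 1, 0);
  int k = 0;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      const int l = lab(r, c);
      if (l == 0) continue;
      const int root = find(l);
      if (newid[root] == 0) newid[root] = ++k;
      lab(r, c) = newid[root];
    }
  }
  return lab;
}
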