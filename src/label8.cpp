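#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Two-pass connected-component labelling of a logical mask with
// 8-connectivity for the foreground (adipocyte) phase. The background
// (matrix) phase is implicitly 4-connected, the standard dual that avoids
// checkerboard ambiguity. Labels are renumbered 1..k in raster order.

static int find_root(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void unite(std::vector<int> &parent, int a, int b) {
  a = find_root(parent, a);
  b = find_root(parent, b);
  if (a != b) parent[std::max(a, b)] = std::min(a, b);
}

// [[Rcpp::export]]
IntegerMatrix label_components_8(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0);  // parent[0] unused
  int next = 1;

  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j)) continue;
      int lmin = 0;
      int neigh[4][2] = {{i - 1, j - 1}, {i - 1, j},
                         {i - 1, j + 1}, {i, j - 1}};
      for (int k = 0; k < 4; ++k) {
        int ni = neigh[k][0], nj = neigh[k][1];
        if (ni < 0 || nj < 0 || nj >= nc) continue;
        int l = lab(ni, nj);
        if (l > 0) {
          if (lmin == 0) lmin = l;
          else unite(parent, lmin, l);
        }
      }
      if (lmin == 0) {
        lmin = next++;
        parent.push_back(lmin);
      }
      lab(i, j) = lmin;
    }
  }

  // Resolve equivalences and renumber compactly in raster order.
  std::vector<int> newlab(next, 0);
  int k = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      int r = find_root(parent, l);
      if (newlab[r] == 0) newlab[r] = ++k;
      lab(i, j) = newlab[r];
    }
  }
  return lab;
}
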