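#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static int uf_find(std::vector<int>& parent, int a) {
  while (parent[a] != a) {
    parent[a] = parent[parent[a]];
    a = parent[a];
  }
  return a;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  a = uf_find(parent, a);
  b = uf_find(parent, b);
  if (a != b) parent[std::max(a, b)] = std::min(a, b);
}

// Connected-component labeling of a binary 3D grid at connectivity 6
// (faces), 18 (faces + edges) or 26 (faces + edges + corners). Two-pass
// union-find; final labels are consecutive from 1 in raster-scan order of
// each component's first voxel (deterministic).
// [[Rcpp::export(name = ".labelComponents3D")]]
List label_components_3d(LogicalVector mask, IntegerVector dims,
                         int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  // neighbor offsets with negative raster order (already-visited half)
  std::vector<int> oz, oy, ox;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (dz == 0 && dy == 0 && dx == 0) continue;
        const int ord = dz + 3 * dy + 9 * dx;  // raster order along (z,y,x)
        if (ord >= 0) continue;                // keep prior-scan half only
        const int man = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (connectivity == 6 && man > 1) continue;
        if (connectivity == 18 && man > 2) continue;
        oz.push_back(dz); oy.push_back(dy); ox.push_back(dx);
      }
  IntegerVector lab(mask.size());
  lab.attr("dim") = dims;
  std::vector<int> parent(1, 0);  // parent[0] unused
  int next = 1;
  for (int k = 0; k < nx; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nz; ++i) {
        const R_xlen_t idx = i + (R_xlen_t)nz * (j + (R_xlen_t)ny * k);
        if (!mask[idx]) continue;
        int best = 0;
        for (size_t q = 0; q < oz.size(); ++q) {
          const int ii = i + oz[q], jj = j + oy[q], kk = k + ox[q];
          if (ii < 0 || ii >= nz || jj < 0 || jj >= ny || kk < 0 || kk >= nx)
            continue;
          const int nl = lab[ii + (R_xlen_t)nz * (jj + (R_xlen_t)ny * kk)];
          if (nl > 0) {
            if (best == 0) best = nl;
            else uf_union(parent, best, nl);
          }
        }
        if (best == 0) {
          parent.push_back(next);
          lab[idx] = next++;
        } else {
          lab[idx] = best;
        }
      }
  // resolve + renumber consecutively in raster order of first appearance
  std::vector<int> remap(parent.size(), 0);
  int nComp = 0;
  for (R_xlen_t idx = 0; idx < lab.size(); ++idx) {
    if (lab[idx] == 0) continue;
    const int root = uf_find(parent, lab[idx]);
    if (remap[root] == 0) remap[root] = ++nComp;
    lab[idx] = remap[root];
  }
  return List::create(_["labels"] = lab, _["n"] = nComp);
}
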