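#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Topology-preserving 3D curve thinning.
//
// A voxel is "simple" (deletable without changing topology) iff, in its
// 3x3x3 neighborhood, the object has exactly one 26-connected component
// among the 26 neighbors AND the background restricted to the
// 18-neighborhood has exactly one 6-connected component that touches a
// face neighbor (topology-number characterization). Thinning proceeds in
// six directional subiterations (U, D, N, S, E, W border voxels),
// deleting sequentially so each deletion re-validates simplicity; curve
// endpoints (exactly one object neighbor) are preserved so fibers thin to
// one-voxel-wide center lines rather than vanishing.

namespace {

// neighborhood cube: local index d = (dz+1) + 3*(dy+1) + 9*(dx+1), 0..26
inline int cubeIdx(int dz, int dy, int dx) {
  return (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1);
}

// 26-adjacency between two cube cells
inline bool adj26(int a, int b) {
  const int az = a % 3, ay = (a / 3) % 3, ax = a / 9;
  const int bz = b % 3, by = (b / 3) % 3, bx = b / 9;
  return std::abs(az - bz) <= 1 && std::abs(ay - by) <= 1 &&
         std::abs(ax - bx) <= 1 && a != b;
}

// 6-adjacency between two cube cells
inline bool adj6(int a, int b) {
  const int az = a % 3, ay = (a / 3) % 3, ax = a / 9;
  const int bz = b % 3, by = (b / 3) % 3, bx = b / 9;
  return std::abs(az - bz) + std::abs(ay - by) + std::abs(ax - bx) == 1;
}

bool isSimple(const bool nb[27]) {
  const int C = 13;  // center
  // C*: 26-components of object among the 26 neighbors
  bool seen[27] = {false};
  int nObjComp = 0, nObj = 0;
  for (int a = 0; a < 27; ++a) if (a != C && nb[a]) ++nObj;
  if (nObj == 0) return false;  // isolated point: not simple
  for (int a = 0; a < 27; ++a) {
    if (a == C || !nb[a] || seen[a]) continue;
    ++nObjComp;
    if (nObjComp > 1) return false;
    std::vector<int> stack(1, a);
    seen[a] = true;
    while (!stack.empty()) {
      const int u = stack.back(); stack.pop_back();
      for (int b = 0; b < 27; ++b) {
        if (b == C || !nb[b] || seen[b] || !adj26(u, b)) continue;
        seen[b] = true;
        stack.push_back(b);
      }
    }
  }
  // C-bar: 6-components of background within the 18-neighborhood that
  // contain a face neighbor of the center
  bool inN18[27] = {false};
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int man = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (man == 1 || man == 2) inN18[cubeIdx(dz, dy, dx)] = true;
      }
  bool seenB[27] = {false};
  int nBgComp = 0;
  for (int a = 0; a < 27; ++a) {
    if (!inN18[a] || nb[a] || seenB[a]) continue;
    // flood this 6-component inside N18
    std::vector<int> stack(1, a);
    seenB[a] = true;
    bool touchesFace = false;
    std::vector<int> comp;
    while (!stack.empty()) {
      const int u = stack.back(); stack.pop_back();
      comp.push_back(u);
      if (adj6(u, C)) touchesFace = true;
      for (int b = 0; b < 27; ++b) {
        if (!inN18[b] || nb[b] || seenB[b] || !adj6(u, b)) continue;
        seenB[b] = true;
        stack.push_back(b);
      }
    }
    if (touchesFace) ++nBgComp;
    if (nBgComp > 1) return false;
  }
  return nObjComp == 1 && nBgComp == 1;
}

}  // namespace

// [[Rcpp::export(name = ".thin3D")]]
LogicalVector thin_3d(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  std::vector<unsigned char> obj(n);
  for (R_xlen_t t = 0; t < n; ++t) obj[t] = mask[t] ? 1 : 0;

  auto at = [&](int i, int j, int k) -> unsigned char {
    if (i < 0 || i >= nz || j < 0 || j >= ny || k < 0 || k >= nx) return 0;
    return obj[i + (R_xlen_t)nz * (j + (R_xlen_t)ny * k)];
  };

  // border directions: (dz,dy,dx) whose neighbor must be background
  const int dir[6][3] = {{-1, 0, 0}, {1, 0, 0}, {0, -1, 0},
                         {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      // collect candidates for this subiteration, then delete sequentially
      std::vector<R_xlen_t> cand;
      for (int k = 0; k < nx; ++k)
        for (int j = 0; j < ny; ++j)
          for (int i = 0; i < nz; ++i) {
            const R_xlen_t idx = i + (R_xlen_t)nz * (j + (R_xlen_t)ny * k);
            if (!obj[idx]) continue;
            if (at(i + dir[d][0], j + dir[d][1], k + dir[d][2])) continue;
            cand.push_back(idx);
          }
      for (R_xlen_t c : cand) {
        const int i = (int)(c % nz);
        const int j = (int)((c / nz) % ny);
        const int k = (int)(c / ((R_xlen_t)nz * ny));
        bool nb[27];
        int nObj = 0;
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dz = -1; dz <= 1; ++dz) {
              const bool v = at(i + dz, j + dy, k + dx) != 0;
              nb[cubeIdx(dz, dy, dx)] = v;
              if (v && !(dz == 0 && dy == 0 && dx == 0)) ++nObj;
            }
        if (nObj == 1) continue;  // curve endpoint: preserve
        if (isSimple(nb)) {
          obj[c] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalVector out(n);
  out.attr("dim") = dims;
  for (R_xlen_t t = 0; t < n; ++t) out[t] = obj[t] != 0;
  return out;
}
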