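#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Accumulate the second-order structure tensor J = sum_w g * (grad I)(grad I)^T
// at each query point over a cubic window of half-size h voxels, Gaussian
// window weight g with standard deviation wsigma (voxels). Windows extending
// beyond the grid are clipped. Points are 0-based (z, y, x) voxel indices.
// Returns an n x 6 matrix (Jxx, Jxy, Jxz, Jyy, Jyz, Jzz).
// [[Rcpp::export(name = ".structureTensorAtPoints")]]
NumericMatrix structure_tensor_at_points(NumericVector gx, NumericVector gy,
                                         NumericVector gz, IntegerVector dims,
                                         IntegerMatrix points, int h,
                                         double wsigma) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int np = points.nrow();
  NumericMatrix out(np, 6);
  const double inv2s2 = 1.0 / (2.0 * wsigma * wsigma);
  for (int p = 0; p < np; ++p) {
    const int pi = points(p, 0), pj = points(p, 1), pk = points(p, 2);
    double jxx = 0, jxy = 0, jxz = 0, jyy = 0, jyz = 0, jzz = 0;
    for (int dk = -h; dk <= h; ++dk) {
      const int k = pk + dk;
      if (k < 0 || k >= nx) continue;
      for (int dj = -h; dj <= h; ++dj) {
        const int j = pj + dj;
        if (j < 0 || j >= ny) continue;
        for (int di = -h; di <= h; ++di) {
          const int i = pi + di;
          if (i < 0 || i >= nz) continue;
          const double w =
              std::exp(-((double)(di * di + dj * dj + dk * dk)) * inv2s2);
          const R_xlen_t idx = i + (R_xlen_t)nz * (j + (R_xlen_t)ny * k);
          const double vx = gx[idx], vy = gy[idx], vz = gz[idx];
          jxx += w * vx * vx;
          jxy += w * vx * vy;
          jxz += w * vx * vz;
          jyy += w * vy * vy;
          jyz += w * vy * vz;
          jzz += w * vz * vz;
        }
      }
    }
    out(p, 0) = jxx; out(p, 1) = jxy; out(p, 2) = jxz;
    out(p, 3) = jyy; out(p, 4) = jyz; out(p, 5) = jzz;
  }
  return out;
}

// Median chord length (voxel units) of diametric rays cast in the plane
// orthogonal to the unit direction rho through each point. Each of nRays
// rays is sampled at `step`-voxel increments outward in both directions
// until the mask is left. A ray that leaves the grid while still inside
// the mask is censored (the chord is clipped by the field of view, not a
// real fiber surface); points with fewer than half their rays uncensored
// return NA, as do points outside the mask.
// [[Rcpp::export(name = ".rayChords")]]
NumericVector ray_chords(LogicalVector mask, IntegerVector dims,
                         IntegerMatrix points, NumericMatrix rho, int nRays,
                         double step) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int np = points.nrow();
  NumericVector out(np);
  // 1 = in mask, 0 = in grid but out of mask, -1 = out of grid
  auto probe = [&](double x, double y, double z) -> int {
    const int k = (int)std::lround(x), j = (int)std::lround(y),
              i = (int)std::lround(z);
    if (i < 0 || i >= nz || j < 0 || j >= ny || k < 0 || k >= nx) return -1;
    return mask[i + (R_xlen_t)nz * (j + (R_xlen_t)ny * k)] ? 1 : 0;
  };
  auto inside = [&](double x, double y, double z) -> bool {
    return probe(x, y, z) == 1;
  };
  std::vector<double> chords;
  for (int p = 0; p < np; ++p) {
    const double pz = points(p, 0), py = points(p, 1), px = points(p, 2);
    const double rx = rho(p, 0), ry = rho(p, 1), rz = rho(p, 2);
    if (!inside(px, py, pz)) {
      out[p] = NA_REAL;
      continue;
    }
    // orthonormal basis (u, v) of the plane orthogonal to rho
    double ux, uy, uz;
    if (std::fabs(rx) <= std::fabs(ry) && std::fabs(rx) <= std::fabs(rz)) {
      ux = 0; uy = -rz; uz = ry;
    } else if (std::fabs(ry) <= std::fabs(rz)) {
      ux = -rz; uy = 0; uz = rx;
    } else {
      ux = -ry; uy = rx; uz = 0;
    }
    const double un = std::sqrt(ux * ux + uy * uy + uz * uz);
    ux /= un; uy /= un; uz /= un;
    const double vx = ry * uz - rz * uy;
    const double vy = rz * ux - rx * uz;
    const double vz = rx * uy - ry * ux;
    chords.clear();
    const double maxT = nx + ny + nz;
    for (int r = 0; r < nRays; ++r) {
      const double a = M_PI * r / nRays;
      const double ex = std::cos(a) * ux + std::sin(a) * vx;
      const double ey = std::cos(a) * uy + std::sin(a) * vy;
      const double ez = std::cos(a) * uz + std::sin(a) * vz;
      double tpos = 0, tneg = 0;
      bool censored = false;
      while (tpos < maxT &&
             inside(px + (tpos + step) * ex, py + (tpos + step) * ey,
                    pz + (tpos + step) * ez))
        tpos += step;
      if (probe(px + (tpos + step) * ex, py + (tpos + step) * ey,
                pz + (tpos + step) * ez) < 0)
        censored = true;
      while (tneg < maxT &&
             inside(px - (tneg + step) * ex, py - (tneg + step) * ey,
                    pz - (tneg + step) * ez))
        tneg += step;
      if (probe(px - (tneg + step) * ex, py - (tneg + step) * ey,
                pz - (tneg + step) * ez) < 0)
        censored = true;
      if (censored) continue;
      // distance between extreme in-mask samples, plus half a step per
      // side (the boundary lies between the last inside and first outside
      // sample); a structure one voxel across has unit physical extent
      chords.push_back(std::max(tpos + tneg + step, 1.0));
    }
    const size_t m = chords.size();
    if ((int)m < (nRays + 1) / 2) {
      out[p] = NA_REAL;
      continue;
    }
    std::sort(chords.begin(), chords.end());
    out[p] = (m % 2 == 1) ? chords[m / 2]
                          : 0.5 * (chords[m / 2 - 1] + chords[m / 2]);
  }
  return out;
}
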