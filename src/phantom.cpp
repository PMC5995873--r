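#include <Rcpp.h>
using namespace Rcpp;

// Voxel grids use R array layout dim = c(nz, ny, nx); linear index
// i + nz*(j + ny*k) for 0-based (i=z, j=y, k=x). Voxel centers sit at
// integer coordinates (x=k, y=j, z=i) in voxel units.

// Rasterize a solid cylinder of radius r (voxel units) around the infinite
// line through (ax,ay,az) with unit direction (dx,dy,dz) into an integer
// phase grid, setting phase to `value` where the voxel center is within r.
// Returns the number of voxels newly set (previous phase != value).
// [[Rcpp::export(name = ".rasterCylinder")]]
int raster_cylinder(IntegerVector phase, IntegerVector dims,
                    double ax, double ay, double az,
                    double dx, double dy, double dz,
                    double r, int value) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double r2 = r * r;
  int nnew = 0;
  for (int k = 0; k < nx; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nz; ++i) {
        const double px = k - ax, py = j - ay, pz = i - az;
        const double t = px * dx + py * dy + pz * dz;
        const double qx = px - t * dx, qy = py - t * dy, qz = pz - t * dz;
        if (qx * qx + qy * qy + qz * qz <= r2) {
          const R_xlen_t idx = i + (R_xlen_t)nz * (j + (R_xlen_t)ny * k);
          if (phase[idx] != value) {
            phase[idx] = value;
            ++nnew;
          }
        }
      }
    }
  }
  return nnew;
}

// Rasterize a solid sphere centered at (cx,cy,cz) with radius r (voxel
// units); sets phase and an aggregate-id grid. Returns the voxel count of
// the sphere (voxels inside, regardless of previous phase).
// [[Rcpp::export(name = ".rasterSphere")]]
int raster_sphere(IntegerVector phase, IntegerVector agg, IntegerVector dims,
                  double cx, double cy, double cz, double r,
                  int value, int aggId) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const double r2 = r * r;
  int count = 0;
  const int k0 = std::max(0, (int)std::floor(cx - r) - 1);
  const int k1 = std::min(nx - 1, (int)std::ceil(cx + r) + 1);
  const int j0 = std::max(0, (int)std::floor(cy - r) - 1);
  const int j1 = std::min(ny - 1, (int)std::ceil(cy + r) + 1);
  const int i0 = std::max(0, (int)std::floor(cz - r) - 1);
  const int i1 = std::min(nz - 1, (int)std::ceil(cz + r) + 1);
  for (int k = k0; k <= k1; ++k) {
    for (int j = j0; j <= j1; ++j) {
      for (int i = i0; i <= i1; ++i) {
        const double px = k - cx, py = j - cy, pz = i - cz;
        if (px * px + py * py + pz * pz <= r2) {
          const R_xlen_t idx = i + (R_xlen_t)nz * (j + (R_xlen_t)ny * k);
          phase[idx] = value;
          agg[idx] = aggId;
          ++count;
        }
      }
    }
  }
  return count;
}
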