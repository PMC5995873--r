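#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Reflective (mirror) index into [0, n): standard edge handling for
// neighborhood filters on finite grids.
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n - 2;
  i = ((i % period) + period) % period;
  return (i < n) ? i : period - i;
}

// 3D median filter over a discrete ball of integer voxel radius. Radius 0
// is the identity. Edges handled by reflective padding. With
// slicewise = true the ball is cut to the slice plane (a disc; dz = 0),
// i.e. each z-slice is filtered independently in 2D.
// [[Rcpp::export(name = ".medianFilterBall")]]
NumericVector median_filter_ball(NumericVector vol, IntegerVector dims,
                                 int radius, bool slicewise = false) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  if (radius <= 0) return clone(vol);
  // precompute ball offsets
  std::vector<int> oz, oy, ox;
  const int r2 = radius * radius;
  for (int dz = -radius; dz <= radius; ++dz)
    for (int dy = -radius; dy <= radius; ++dy)
      for (int dx = -radius; dx <= radius; ++dx)
        if (dz * dz + dy * dy + dx * dx <= r2) {
          if (slicewise && dz != 0) continue;
          oz.push_back(dz); oy.push_back(dy); ox.push_back(dx);
        }
  const size_t m = oz.size();
  NumericVector out(vol.size());
  out.attr("dim") = dims;
  std::vector<double> buf(m);
  for (int k = 0; k < nx; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nz; ++i) {
        for (size_t q = 0; q < m; ++q) {
          const int ii = reflect(i + oz[q], nz);
          const int jj = reflect(j + oy[q], ny);
          const int kk = reflect(k + ox[q], nx);
          buf[q] = vol[ii + (R_xlen_t)nz * (jj + (R_xlen_t)ny * kk)];
        }
        std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
        double med = buf[m / 2];
        if (m % 2 == 0) {
          double lo = *std::max_element(buf.begin(), buf.begin() + m / 2);
          med = 0.5 * (med + lo);
        }
        out[i + (R_xlen_t)nz * (j + (R_xlen_t)ny * k)] = med;
      }
    }
  }
  return out;
}

// Separable 1D convolution along one axis (0 = z, 1 = y, 2 = x) with an
// odd-length kernel, reflective padding. Kernel center at (len-1)/2.
// [[Rcpp::export(name = ".convolveAxis")]]
NumericVector convolve_axis(NumericVector vol, IntegerVector dims,
                            NumericVector kernel, int axis) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int klen = kernel.size();
  const int kc = (klen - 1) / 2;
  NumericVector out(vol.size());
  out.attr("dim") = dims;
  for (int k = 0; k < nx; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nz; ++i) {
        double acc = 0.0;
        for (int q = 0; q < klen; ++q) {
          const int off = q - kc;
          int ii = i, jj = j, kk = k;
          if (axis == 0) ii = reflect(i + off, nz);
          else if (axis == 1) jj = reflect(j + off, ny);
          else kk = reflect(k + off, nx);
          acc += kernel[q] * vol[ii + (R_xlen_t)nz * (jj + (R_xlen_t)ny * kk)];
        }
        out[i + (R_xlen_t)nz * (j + (R_xlen_t)ny * k)] = acc;
      }
    }
  }
  return out;
}
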