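// Separable Gaussian blur (reflective boundaries) and trilinear resampling.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int reflect(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// [[Rcpp::export]]
NumericVector cpp_gauss_blur(NumericVector img, IntegerVector dim,
                             double sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  if (sigma_vox <= 0) return clone(img);
  int R = std::max(1, (int)std::ceil(3.0 * sigma_vox));
  std::vector<double> k(2 * R + 1);
  double s = 0;
  for (int i = -R; i <= R; ++i) {
    k[i + R] = std::exp(-0.5 * (double)i * i / (sigma_vox * sigma_vox));
    s += k[i + R];
  }
  for (int i = 0; i < 2 * R + 1; ++i) k[i] /= s;

  std::vector<double> a(img.begin(), img.end()), b(n);
  // x pass
  for (int zz = 0; zz < nz; ++zz)
    for (int yy = 0; yy < ny; ++yy) {
      size_t base = (size_t)nx * (yy + (size_t)ny * zz);
      for (int x = 0; x < nx; ++x) {
        double acc = 0;
        for (int d = -R; d <= R; ++d) acc += k[d + R] * a[base + reflect(x + d, nx)];
        b[base + x] = acc;
      }
    }
  // y pass
  for (int zz = 0; zz < nz; ++zz)
    for (int x = 0; x < nx; ++x) {
      size_t base = x + (size_t)nx * ny * zz;
      for (int y = 0; y < ny; ++y) {
        double acc = 0;
        for (int d = -R; d <= R; ++d)
          acc += k[d + R] * b[base + (size_t)nx * reflect(y + d, ny)];
        a[x + (size_t)nx * (y + (size_t)ny * zz)] = acc;
      }
    }
  // z pass
  size_t sl = (size_t)nx * ny;
  for (int yy = 0; yy < ny; ++yy)
    for (int x = 0; x < nx; ++x) {
      size_t base = x + (size_t)nx * yy;
      for (int z = 0; z < nz; ++z) {
        double acc = 0;
        for (int d = -R; d <= R; ++d) acc += k[d + R] * a[base + sl * reflect(z + d, nz)];
        b[base + sl * z] = acc;
      }
    }
  return NumericVector(b.begin(), b.end());
}

// Resample by scale = target_spacing / source_spacing (>= 1). New voxel
// centre i maps to source coordinate (i + 0.5) * scale - 0.5 (0-based),
// clamped, trilinear interpolation.
// [[Rcpp::export]]
NumericVector cpp_resample_trilinear(NumericVector img, IntegerVector dim,
                                     IntegerVector newdim, double scale) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int mx = newdim[0], my = newdim[1], mz = newdim[2];
  NumericVector out((size_t)mx * my * mz);
  for (int z = 0; z < mz; ++z) {
    double sz = (z + 0.5) * scale - 0.5;
    if (sz < 0) sz = 0;
    if (sz > nz - 1) sz = nz - 1;
    int z0 = (int)sz, z1 = std::min(z0 + 1, nz - 1);
    double fz = sz - z0;
    for (int y = 0; y < my; ++y) {
      double sy = (y + 0.5) * scale - 0.5;
      if (sy < 0) sy = 0;
      if (sy > ny - 1) sy = ny - 1;
      int y0 = (int)sy, y1 = std::min(y0 + 1, ny - 1);
      double fy = sy - y0;
      for (int x = 0; x < mx; ++x) {
        double sx = (x + 0.5) * scale - 0.5;
        if (sx < 0) sx = 0;
        if (sx > nx - 1) sx = nx - 1;
        int x0 = (int)sx, x1 = std::min(x0 + 1, nx - 1);
        double fx = sx - x0;
        size_t i000 = x0 + (size_t)nx * (y0 + (size_t)ny * z0);
        size_t i100 = x1 + (size_t)nx * (y0 + (size_t)ny * z0);
        size_t i010 = x0 + (size_t)nx * (y1 + (size_t)ny * z0);
        size_t i110 = x1 + (size_t)nx * (y1 + (size_t)ny * z0);
        size_t i001 = x0 + (size_t)nx * (y0 + (size_t)ny * z1);
        size_t i101 = x1 + (size_t)nx * (y0 + (size_t)ny * z1);
        size_t i011 = x0 + (size_t)nx * (y1 + (size_t)ny * z1);
        size_t i111 = x1 + (size_t)nx * (y1 + (size_t)ny * z1);
        double c00 = img[i000] * (1 - fx) + img[i100] * fx;
        double c10 = img[i010] * (1 - fx) + img[i110] * fx;
        double c01 = img[i001] * (1 - fx) + img[i101] * fx;
        double c11 = img[i011] * (1 - fx) + img[i111] * fx;
        double c0 = c00 * (1 - fy) + c10 * fy;
        double c1 = c01 * (1 - fy) + c11 * fy;
        out[x + (size_t)mx * (y + (size_t)my * z)] = c0 * (1 - fz) + c1 * fz;
      }
    }
  }
  return out;
}
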