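// Voxel kernels: exact squared Euclidean distance transform, maximal
// inscribed sphere local thickness, 26-connected labeling, neighbor counts.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double DT_INF = 1e15;

// 1D squared distance transform along a sampled line (Felzenszwalb &
// Huttenlocher lower envelope of parabolas). f: input costs, d: output.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s;
    for (;;) {
      int p = v[k];
      s = ((f[q] + (double)q * q) - (f[p] + (double)p * p)) / (2.0 * (q - p));
      if (s > z[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

static void edt_pass(std::vector<double>& g, int nx, int ny, int nz, int axis) {
  int n = axis == 0 ? nx : (axis == 1 ? ny : nz);
  std::vector<double> f(n), d(n), z(n + 1);
  std::vector<int> v(n);
  if (axis == 0) {
    for (int zz = 0; zz < nz; ++zz)
      for (int yy = 0; yy < ny; ++yy) {
        size_t base = (size_t)nx * (yy + (size_t)ny * zz);
        for (int i = 0; i < n; ++i) f[i] = g[base + i];
        dt1d(f, d, v, z, n);
        for (int i = 0; i < n; ++i) g[base + i] = d[i];
      }
  } else if (axis == 1) {
    for (int zz = 0; zz < nz; ++zz)
      for (int xx = 0; xx < nx; ++xx) {
        size_t base = xx + (size_t)nx * ny * zz;
        for (int i = 0; i < n; ++i) f[i] = g[base + (size_t)nx * i];
        dt1d(f, d, v, z, n);
        for (int i = 0; i < n; ++i) g[base + (size_t)nx * i] = d[i];
      }
  } else {
    size_t sl = (size_t)nx * ny;
    for (int yy = 0; yy < ny; ++yy)
      for (int xx = 0; xx < nx; ++xx) {
        size_t base = xx + (size_t)nx * yy;
        for (int i = 0; i < n; ++i) f[i] = g[base + sl * i];
        dt1d(f, d, v, z, n);
        for (int i = 0; i < n; ++i) g[base + sl * i] = d[i];
      }
  }
}

// Squared distance (voxel units) from each voxel to the nearest zero voxel.
// Voxels beyond the grid faces are not treated as background, i.e. the
// structure is assumed to continue across the volume-of-interest cut.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector structure, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> g(n);
  for (size_t i = 0; i < n; ++i) g[i] = structure[i] ? DT_INF : 0.0;
  edt_pass(g, nx, ny, nz, 0);
  edt_pass(g, nx, ny, nz, 1);
  edt_pass(g, nx, ny, nz, 2);
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = g[i];
  return out;
}

// Local thickness map (maximal inscribed sphere diameter, voxel units).
// r(c) = sqrt(EDT^2) - 0.5 (distance to the phase boundary); every structure
// voxel x receives 2 * max{ r(c) : |x - c| <= r(c) }. A distance-ridge
// reduction drops centres whose sphere is contained in a neighbour's.
// [[Rcpp::export]]
NumericVector cpp_local_thickness(LogicalVector structure, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector d2 = cpp_edt_sq(structure, dim);
  std::vector<float> r(n, 0.0f);
  for (size_t i = 0; i < n; ++i)
    if (structure[i]) r[i] = (float)std::sqrt(d2[i]);

  // distance ridge: keep c unless some 26-neighbour n has r[n] >= r[c] + |cn|
  std::vector<size_t> centers;
  centers.reserve(n / 8 + 1);
  for (int zz = 0; zz < nz; ++zz)
    for (int yy = 0; yy < ny; ++yy)
      for (int xx = 0; xx < nx; ++xx) {
        size_t i = xx + (size_t)nx * (yy + (size_t)ny * zz);
        if (!structure[i]) continue;
        bool covered = false;
        for (int dz = -1; dz <= 1 && !covered; ++dz)
          for (int dy = -1; dy <= 1 && !covered; ++dy)
            for (int dx = -1; dx <= 1 && !covered; ++dx) {
              if (!dx && !dy && !dz) continue;
              int x2 = xx + dx, y2 = yy + dy, z2 = zz + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                continue;
              size_t j = x2 + (size_t)nx * (y2 + (size_t)ny * z2);
              if (!structure[j]) continue;
              double dist = std::sqrt((double)(dx * dx + dy * dy + dz * dz));
              if ((double)r[j] >= (double)r[i] + dist - 1e-9) covered = true;
            }
        if (!covered) centers.push_back(i);
      }
  std::sort(centers.begin(), centers.end(), [&](size_t a, size_t b) {
    if (r[a] != r[b]) return r[a] > r[b];
    return a < b;
  });

  // Spheres are painted in decreasing radius order, so a voxel's final value
  // is set by the first sphere that reaches it. An interval union-find
  // ("next unwritten voxel at or after i") lets each row segment of a sphere
  // walk only voxels that still need a value, making the painting
  // O(sum of sphere cross-sections) instead of O(sum of sphere volumes).
  NumericVector th(n);
  std::vector<int> nxt(n + 1);
  for (size_t i = 0; i <= n; ++i) nxt[i] = (int)i;
  for (size_t i = 0; i < n; ++i)
    if (!structure[i]) nxt[i] = (int)i + 1;  // never written
  auto find = [&](int i) {
    while (nxt[i] != i) {
      nxt[i] = nxt[nxt[i]];
      i = nxt[i];
    }
    return i;
  };

  for (size_t ci = 0; ci < centers.size(); ++ci) {
    size_t c = centers[ci];
    double rc = (double)r[c] - 0.5;
    if (rc < 0.5) rc = 0.5;  // a voxel always holds its one-voxel sphere
    double diam = 2.0 * rc;
    int cz = (int)(c / ((size_t)nx * ny));
    int cy = (int)((c / nx) % ny);
    int cx = (int)(c % nx);
    double rc2 = rc * rc + 1e-9;
    int R = (int)std::floor(rc + 1e-9);
    for (int dz = -R; dz <= R; ++dz) {
      int z2 = cz + dz;
      if (z2 < 0 || z2 >= nz) continue;
      for (int dy = -R; dy <= R; ++dy) {
        int y2 = cy + dy;
        if (y2 < 0 || y2 >= ny) continue;
        double dd = (double)dz * dz + (double)dy * dy;
        if (dd > rc2) continue;
        int mx = (int)std::floor(std::sqrt(rc2 - dd));
        int x0 = std::max(0, cx - mx), x1 = std::min(nx - 1, cx + mx);
        size_t base = (size_t)nx * (y2 + (size_t)ny * z2);
        int a = (int)(base + x0), b = (int)(base + x1);
        for (int i = find(a); i <= b; i = find(i + 1)) {
          th[i] = diam;
          nxt[i] = i + 1;
        }
      }
    }
  }
  return th;
}

// 26-connected component labels (0 = background), deterministic scan order.
// [[Rcpp::export]]
IntegerVector cpp_label26(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n);
  std::vector<size_t> stack;
  int next = 0;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      size_t i = stack.back();
      stack.pop_back();
      int zz = (int)(i / ((size_t)nx * ny));
      int yy = (int)((i / nx) % ny);
      int xx = (int)(i % nx);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int x2 = xx + dx, y2 = yy + dy, z2 = zz + dz;
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
              continue;
            size_t j = x2 + (size_t)nx * (y2 + (size_t)ny * z2);
            if (mask[j] && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
    }
  }
  return lab;
}

// Number of 26-neighbours set in `mask`, for every voxel of `mask`
// (0 elsewhere). Out-of-grid voxels count as unset.
// [[Rcpp::export]]
IntegerVector cpp_neighbor_count26(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector cnt(n);
  for (int zz = 0; zz < nz; ++zz)
    for (int yy = 0; yy < ny; ++yy)
      for (int xx = 0; xx < nx; ++xx) {
        size_t i = xx + (size_t)nx * (yy + (size_t)ny * zz);
        if (!mask[i]) continue;
        int c = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int x2 = xx + dx, y2 = yy + dy, z2 = zz + dz;
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
                continue;
              if (mask[x2 + (size_t)nx * (y2 + (size_t)ny * z2)]) ++c;
            }
        cnt[i] = c;
      }
  return cnt;
}
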