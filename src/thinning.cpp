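// Sequential 6-directional topology-preserving 3D thinning.
//
// A voxel is deleted only while it is a simple point: exactly one
// 26-connected foreground component in its 26-neighbourhood and exactly one
// 6-connected background component in its 18-neighbourhood touching a face
// neighbour (Bertrand/Malandain characterization). Curve endpoints (<= 1
// foreground 26-neighbour) are preserved. Voxels beyond the grid faces are
// treated as foreground so structures cut by the volume of interest are not
// eroded from the artificial cut faces; one-voxel-thick medial plates are
// non-simple in their interior and survive as medial surfaces.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Grid {
  const int* img;  // 0/1 working copy
  int nx, ny, nz;
  // out-of-grid voxels are foreground (structure continues past the VOI cut)
  inline int at(int x, int y, int z) const {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return 1;
    return img[x + (size_t)nx * (y + (size_t)ny * z)];
  }
};

// fill local 3x3x3 occupancy, index (dx+1) + 3*(dy+1) + 9*(dz+1)
inline void neighborhood(const Grid& g, int x, int y, int z, int* nb) {
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) nb[k++] = g.at(x + dx, y + dy, z + dz);
}

inline int lidx(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

// number of foreground voxels among the 26 neighbours
inline int fg_count(const int* nb) {
  int c = 0;
  for (int i = 0; i < 27; ++i)
    if (i != 13 && nb[i]) ++c;
  return c;
}

// one 26-connected foreground component among the 26 neighbours?
bool one_fg_component(const int* nb) {
  int seen[27] = {0};
  int comps = 0;
  int stack[27];
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++comps;
    if (comps > 1) return false;
    int top = 0;
    stack[top++] = s;
    seen[s] = 1;
    while (top) {
      int i = stack[--top];
      int ix = i % 3, iy = (i / 3) % 3, iz = i / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int jx = ix + dx, jy = iy + dy, jz = iz + dz;
            if (jx < 0 || jx > 2 || jy < 0 || jy > 2 || jz < 0 || jz > 2)
              continue;
            int j = jx + 3 * jy + 9 * jz;
            if (j == 13 || j == i || !nb[j] || seen[j]) continue;
            seen[j] = 1;
            stack[top++] = j;
          }
    }
  }
  return comps == 1;
}

// one 6-connected background component within the 18-neighbourhood that
// contains a face neighbour of the centre?
bool one_bg_component(const int* nb) {
  // 18-neighbourhood cells: |dx|+|dy|+|dz| <= 2, excluding the centre
  int in18[27];
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int i = lidx(dx, dy, dz);
        int m = (dx < 0 ? -dx : dx) + (dy < 0 ? -dy : dy) + (dz < 0 ? -dz : dz);
        in18[i] = (m >= 1 && m <= 2);
      }
  static const int faces[6] = {lidx(-1, 0, 0), lidx(1, 0, 0), lidx(0, -1, 0),
                               lidx(0, 1, 0),  lidx(0, 0, -1), lidx(0, 0, 1)};
  int seen[27] = {0};
  int comps = 0;
  int stack[27];
  for (int f = 0; f < 6; ++f) {
    int s = faces[f];
    if (nb[s] || seen[s]) continue;  // background faces only, unvisited
    ++comps;
    if (comps > 1) return false;
    int top = 0;
    stack[top++] = s;
    seen[s] = 1;
    while (top) {
      int i = stack[--top];
      int ix = i % 3, iy = (i / 3) % 3, iz = i / 9;
      static const int D[6][3] = {{-1, 0, 0}, {1, 0, 0},  {0, -1, 0},
                                  {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
      for (int d = 0; d < 6; ++d) {
        int jx = ix + D[d][0], jy = iy + D[d][1], jz = iz + D[d][2];
        if (jx < 0 || jx > 2 || jy < 0 || jy > 2 || jz < 0 || jz > 2) continue;
        int j = jx + 3 * jy + 9 * jz;
        if (j == 13 || !in18[j] || nb[j] || seen[j]) continue;
        seen[j] = 1;
        stack[top++] = j;
      }
    }
  }
  return comps == 1;
}

inline bool is_simple(const Grid& g, int x, int y, int z) {
  int nb[27];
  neighborhood(g, x, y, z, nb);
  return one_fg_component(nb) && one_bg_component(nb);
}

inline int count26(const Grid& g, int x, int y, int z) {
  int nb[27];
  neighborhood(g, x, y, z, nb);
  return fg_count(nb);
}

}  // namespace

// [[Rcpp::export]]
LogicalVector cpp_skeletonize(LogicalVector bone, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<int> img(n);
  for (size_t i = 0; i < n; ++i) img[i] = bone[i] ? 1 : 0;
  Grid g{img.data(), nx, ny, nz};

  static const int D[6][3] = {{0, 0, -1}, {0, 0, 1},  {0, -1, 0},
                              {0, 1, 0},  {-1, 0, 0}, {1, 0, 0}};
  std::vector<size_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int zz = 0; zz < nz; ++zz)
        for (int yy = 0; yy < ny; ++yy)
          for (int xx = 0; xx < nx; ++xx) {
            size_t i = xx + (size_t)nx * (yy + (size_t)ny * zz);
            if (!img[i]) continue;
            int x2 = xx + D[d][0], y2 = yy + D[d][1], z2 = zz + D[d][2];
            // border in direction d: in-grid background face neighbour
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
              continue;
            if (img[x2 + (size_t)nx * (y2 + (size_t)ny * z2)]) continue;
            // never erode one-sidedly against a volume face: if the voxel
            // opposite to d is out of grid, the medial locus of the
            // (continuing) structure lies on or beyond the cut
            int xo = xx - D[d][0], yo = yy - D[d][1], zo = zz - D[d][2];
            if (xo < 0 || xo >= nx || yo < 0 || yo >= ny || zo < 0 || zo >= nz)
              continue;
            cand.push_back(i);
          }
      for (size_t k = 0; k < cand.size(); ++k) {
        size_t i = cand[k];
        if (!img[i]) continue;
        int zz = (int)(i / ((size_t)nx * ny));
        int yy = (int)((i / nx) % ny);
        int xx = (int)(i % nx);
        if (count26(g, xx, yy, zz) < 2) continue;  // preserve curve endpoints
        if (!is_simple(g, xx, yy, zz)) continue;
        img[i] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = img[i] != 0;
  return out;
}
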