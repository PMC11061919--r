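// Region growing kernel for the automated-region-growing segmentation.
//
// Two regions (bone = 1, background = 2) grow alternately from their seed
// sets inside the VOI. Within a turn the frontier is processed as a FIFO
// queue in ascending linear-index order; a voxel joins when its intensity is
// within t_abs of the running region mean, which is updated incrementally.
// Voxels rejected in one turn are reconsidered in later rounds (the mean
// drifts as the region grows). Rounds repeat, bone first, until neither
// region grows. Fully deterministic.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_grow_regions(NumericVector img, IntegerVector assign0,
                      IntegerVector dim, double t_abs, int connectivity,
                      int max_rounds) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<int> assign(n);
  double sum[3] = {0, 0, 0};
  size_t cnt[3] = {0, 0, 0};
  for (size_t i = 0; i < n; ++i) {
    assign[i] = assign0[i];
    if (assign[i] == 1 || assign[i] == 2) {
      sum[assign[i]] += img[i];
      ++cnt[assign[i]];
    }
  }

  std::vector<int> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        if (connectivity == 6 && (std::abs(dx) + std::abs(dy) + std::abs(dz)) != 1)
          continue;
        off.push_back(dx);
        off.push_back(dy);
        off.push_back(dz);
      }
  int noff = (int)off.size() / 3;

  std::vector<uint8_t> inq(n, 0);
  std::vector<size_t> queue;
  queue.reserve(n / 4 + 16);

  int rounds = 0;
  bool grew_any = true;
  while (grew_any && rounds < max_rounds) {
    grew_any = false;
    ++rounds;
    for (int region = 1; region <= 2; ++region) {
      if (cnt[region] == 0) continue;
      queue.clear();
      // frontier: unassigned VOI voxels adjacent to the region, scan order
      for (int zz = 0; zz < nz; ++zz)
        for (int yy = 0; yy < ny; ++yy)
          for (int xx = 0; xx < nx; ++xx) {
            size_t i = xx + (size_t)nx * (yy + (size_t)ny * zz);
            if (assign[i] != 0) continue;
            for (int k = 0; k < noff; ++k) {
              int x2 = xx + off[3 * k], y2 = yy + off[3 * k + 1],
                  z2 = zz + off[3 * k + 2];
              if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 ||
                  z2 >= nz)
                continue;
              if (assign[x2 + (size_t)nx * (y2 + (size_t)ny * z2)] == region) {
                queue.push_back(i);
                inq[i] = 1;
                break;
              }
            }
          }
      size_t head = 0;
      while (head < queue.size()) {
        size_t v = queue[head++];
        if (assign[v] != 0) continue;
        double mean = sum[region] / (double)cnt[region];
        if (std::fabs(img[v] - mean) <= t_abs) {
          assign[v] = region;
          sum[region] += img[v];
          ++cnt[region];
          grew_any = true;
          int zz = (int)(v / ((size_t)nx * ny));
          int yy = (int)((v / nx) % ny);
          int xx = (int)(v % nx);
          for (int k = 0; k < noff; ++k) {
            int x2 = xx + off[3 * k], y2 = yy + off[3 * k + 1],
                z2 = zz + off[3 * k + 2];
            if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
              continue;
            size_t j = x2 + (size_t)nx * (y2 + (size_t)ny * z2);
            if (assign[j] == 0 && !inq[j]) {
              queue.push_back(j);
              inq[j] = 1;
            }
          }
        }
      }
      for (size_t k = 0; k < queue.size(); ++k) inq[queue[k]] = 0;
    }
  }

  IntegerVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = assign[i];
  return List::create(
      _["assign"] = out,
      _["mean_bone"] = cnt[1] ? sum[1] / (double)cnt[1] : NA_REAL,
      _["mean_background"] = cnt[2] ? sum[2] / (double)cnt[2] : NA_REAL,
      _["rounds"] = rounds);
}
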