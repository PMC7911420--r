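// Threshold-free cluster enhancement on a 3D statistic volume.
//
// For each threshold h = dh, 2dh, ... <= max(stat), voxels above h are
// grouped into connected components (6/18/26 neighbourhood); every member
// voxel accumulates e(h)^E * h^H * dh, where e(h) is its component size.
// Negative values are handled by the R wrapper (enhance -stat and negate).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static int find_root(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void unite(std::vector<int>& parent, int a, int b) {
  a = find_root(parent, a);
  b = find_root(parent, b);
  if (a != b) parent[b] = a;
}

// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector dims, double E,
                       double H, double dh, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  NumericVector out(n);
  double mx = 0.0;
  for (int i = 0; i < n; ++i) if (stat[i] > mx) mx = stat[i];
  if (mx <= 0.0 || dh <= 0.0) return out;

  // neighbour offsets for the requested connectivity
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }

  std::vector<int> parent(n);
  std::vector<double> csize(n);

  for (double h = dh; h <= mx + 1e-12; h += dh) {
    for (int i = 0; i < n; ++i) parent[i] = i;
    // union pass over suprathreshold voxels
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = x + nx * (y + ny * z);
          if (stat[i] < h) continue;
          for (size_t q = 0; q < dxs.size(); ++q) {
            int xx = x + dxs[q], yy = y + dys[q], zz = z + dzs[q];
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny ||
                zz >= nz)
              continue;
            int j = xx + nx * (yy + ny * zz);
            if (stat[j] >= h) unite(parent, i, j);
          }
        }
    std::fill(csize.begin(), csize.end(), 0.0);
    for (int i = 0; i < n; ++i)
      if (stat[i] >= h) csize[find_root(parent, i)] += 1.0;
    const double hp = std::pow(h, H) * dh;
    for (int i = 0; i < n; ++i)
      if (stat[i] >= h)
        out[i] += std::pow(csize[find_root(parent, i)], E) * hp;
  }
  return out;
}
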