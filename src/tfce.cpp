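#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Union-find with union by size and path halving.
static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// Threshold-free cluster enhancement of the positive part of a 3D map.
//
// TFCE(p) = sum over h = dh, 2dh, ..., h_max of e(h,p)^E * h^H * dh, where
// e(h,p) is the voxel count of the connected component containing p in the
// supra-threshold set {stat >= h} restricted to the mask, and
// dh = h_max / n_steps. Components are tracked incrementally from the
// highest threshold down, so each voxel is merged into the structure once.
// [[Rcpp::export]]
NumericVector tfce_positive_cpp(NumericVector stat, LogicalVector mask,
                                IntegerVector dims, double E, double H,
                                int n_steps, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  if (stat.size() != n || mask.size() != n)
    stop("stat/mask size does not match dims");
  if (n_steps < 1) stop("n_steps must be >= 1");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  NumericVector out(n, 0.0);

  double h_max = 0.0;
  for (int i = 0; i < n; ++i)
    if (mask[i] && stat[i] > h_max) h_max = stat[i];
  if (h_max <= 0.0) return out;
  const double dh = h_max / n_steps;

  // In-mask positive voxels sorted by height, descending.
  std::vector<int> order;
  order.reserve(n);
  for (int i = 0; i < n; ++i)
    if (mask[i] && stat[i] > 0.0) order.push_back(i);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return stat[a] > stat[b]; });

  // Neighbour offsets for the requested connectivity.
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int nonzero = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (nonzero == 0) continue;
        if (connectivity == 6 && nonzero > 1) continue;
        if (connectivity == 18 && nonzero > 2) continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }

  std::vector<int> parent(n, -1);   // -1: not yet activated
  std::vector<int> csize(n, 0);
  std::vector<char> active(n, 0);

  size_t next = 0;  // next voxel in `order` to activate
  for (int step = n_steps; step >= 1; --step) {
    // the top threshold is h_max itself; computing it as n_steps * dh can
    // round a last bit above h_max and spuriously empty the supra set
    const double h = (step == n_steps) ? h_max : step * dh;
    // Activate voxels with stat >= h and merge with active neighbours.
    while (next < order.size() && stat[order[next]] >= h) {
      const int idx = order[next];
      parent[idx] = idx;
      csize[idx] = 1;
      active[idx] = 1;
      const int z = idx / (nx * ny);
      const int y = (idx / nx) % ny;
      const int x = idx % nx;
      for (size_t k = 0; k < dxs.size(); ++k) {
        const int xx = x + dxs[k], yy = y + dys[k], zz = z + dzs[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        const int j = xx + nx * (yy + ny * zz);
        if (!active[j]) continue;
        int ra = uf_find(parent, idx);
        int rb = uf_find(parent, j);
        if (ra != rb) {
          if (csize[ra] < csize[rb]) std::swap(ra, rb);
          parent[rb] = ra;
          csize[ra] += csize[rb];
        }
      }
      ++next;
    }
    // Accumulate this threshold's contribution for every supra voxel.
    const double hH = std::pow(h, H) * dh;
    for (size_t k = 0; k < next; ++k) {
      const int idx = order[k];
      const int root = uf_find(parent, idx);
      out[idx] += std::pow((double)csize[root], E) * hH;
    }
  }
  return out;
}
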