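// Solvent-accessible-surface distance: 26-connected uniform-cost search
// over an occupancy grid. A cell is blocked when its center lies within
// (van der Waals radius + probe radius) of any obstacle atom. Endpoints
// snap to the nearest free cell; the snap offsets are added to the
// returned path length.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

struct Node {
  double d;
  int idx;
  bool operator<(const Node &o) const { return d > o.d; }
};

static inline int cell_index(int ix, int iy, int iz, int nx, int ny) {
  return ix + nx * (iy + ny * iz);
}

// [[Rcpp::export(name = ".sas_grid_path")]]
List sas_grid_path(NumericMatrix atoms, NumericVector radii,
                   NumericVector src, NumericVector dst,
                   double spacing, double probe, double margin,
                   double max_dist, double snap_max) {
  const int natoms = atoms.nrow();
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) {
    lo[k] = std::min(src[k], dst[k]);
    hi[k] = std::max(src[k], dst[k]);
  }
  for (int a = 0; a < natoms; ++a)
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], atoms(a, k));
      hi[k] = std::max(hi[k], atoms(a, k));
    }
  for (int k = 0; k < 3; ++k) { lo[k] -= margin; hi[k] += margin; }

  int dims[3];
  for (int k = 0; k < 3; ++k)
    dims[k] = (int)std::floor((hi[k] - lo[k]) / spacing) + 1;
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long long ncell = (long long)nx * ny * nz;
  if (ncell > 60000000LL)
    stop("SAS grid too large (%lld cells); increase grid_spacing or reduce margin",
         ncell);

  std::vector<char> blocked((size_t)ncell, 0);
  for (int a = 0; a < natoms; ++a) {
    const double r = radii[a] + probe;
    const double r2 = r * r;
    int clo[3], chi[3];
    for (int k = 0; k < 3; ++k) {
      clo[k] = std::max(0, (int)std::floor((atoms(a, k) - r - lo[k]) / spacing));
      chi[k] = std::min(dims[k] - 1,
                        (int)std::ceil((atoms(a, k) + r - lo[k]) / spacing));
    }
    for (int iz = clo[2]; iz <= chi[2]; ++iz) {
      const double dz = lo[2] + iz * spacing - atoms(a, 2);
      for (int iy = clo[1]; iy <= chi[1]; ++iy) {
        const double dy = lo[1] + iy * spacing - atoms(a, 1);
        const double dzy = dz * dz + dy * dy;
        if (dzy > r2) continue;
        for (int ix = clo[0]; ix <= chi[0]; ++ix) {
          const double dx = lo[0] + ix * spacing - atoms(a, 0);
          if (dx * dx + dzy <= r2)
            blocked[cell_index(ix, iy, iz, nx, ny)] = 1;
        }
      }
    }
  }

  // snap an endpoint to the nearest free cell within snap_max
  auto snap = [&](const NumericVector &pt, int *out_idx, double *out_off) -> bool {
    int c[3];
    for (int k = 0; k < 3; ++k) {
      c[k] = (int)std::round((pt[k] - lo[k]) / spacing);
      if (c[k] < 0 || c[k] >= dims[k]) return false;
    }
    const int rad = (int)std::ceil(snap_max / spacing);
    double best = std::numeric_limits<double>::infinity();
    int best_idx = -1;
    for (int dz = -rad; dz <= rad; ++dz)
      for (int dy = -rad; dy <= rad; ++dy)
        for (int dx = -rad; dx <= rad; ++dx) {
          const int ix = c[0] + dx, iy = c[1] + dy, iz = c[2] + dz;
          if (ix < 0 || iy < 0 || iz < 0 ||
              ix >= nx || iy >= ny || iz >= nz) continue;
          const int idx = cell_index(ix, iy, iz, nx, ny);
          if (blocked[idx]) continue;
          const double ox = lo[0] + ix * spacing - pt[0];
          const double oy = lo[1] + iy * spacing - pt[1];
          const double oz = lo[2] + iz * spacing - pt[2];
          const double off = std::sqrt(ox * ox + oy * oy + oz * oz);
          if (off < best && off <= snap_max) { best = off; best_idx = idx; }
        }
    if (best_idx < 0) return false;
    *out_idx = best_idx;
    *out_off = best;
    return true;
  };

  int src_idx, dst_idx;
  double src_off, dst_off;
  if (!snap(src, &src_idx, &src_off) || !snap(dst, &dst_idx, &dst_off))
    return List::create(_["distance"] = NA_REAL, _["status"] = "buried");

  // 26-neighbour offsets and step costs
  std::vector<int> noff;
  std::vector<double> ncost;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        noff.push_back(dx);
        noff.push_back(dy);
        noff.push_back(dz);
        ncost.push_back(spacing * std::sqrt((double)(dx * dx + dy * dy + dz * dz)));
      }

  std::vector<double> dist((size_t)ncell,
                           std::numeric_limits<double>::infinity());
  std::priority_queue<Node> pq;
  dist[src_idx] = 0.0;
  pq.push({0.0, src_idx});
  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    if (nd.idx == dst_idx) break;
    if (nd.d > dist[nd.idx]) continue;
    if (nd.d > max_dist) break;
    const int iz = nd.idx / (nx * ny);
    const int iy = (nd.idx / nx) % ny;
    const int ix = nd.idx % nx;
    for (size_t t = 0; t < ncost.size(); ++t) {
      const int jx = ix + noff[3 * t], jy = iy + noff[3 * t + 1],
                jz = iz + noff[3 * t + 2];
      if (jx < 0 || jy < 0 || jz < 0 || jx >= nx || jy >= ny || jz >= nz)
        continue;
      const int jdx = cell_index(jx, jy, jz, nx, ny);
      if (blocked[jdx]) continue;
      const double cand = nd.d + ncost[t];
      if (cand < dist[jdx]) {
        dist[jdx] = cand;
        pq.push({cand, jdx});
      }
    }
  }

  const double d = dist[dst_idx];
  if (!std::isfinite(d) || d + src_off + dst_off > max_dist)
    return List::create(_["distance"] = NA_REAL, _["status"] = "unreachable");
  return List::create(_["distance"] = d + src_off + dst_off,
                      _["status"] = "ok");
}
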