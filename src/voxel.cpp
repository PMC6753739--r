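#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Capsule-union rasterization and signed-distance sampling.
//
// Primitives are capsules (branch segments carrying a radius) and spheres
// (joint caps). A uniform coarse binning of radius-expanded bounding boxes
// accelerates point queries; every query point only tests the primitives
// binned at its coarse cell.

static inline double seg_dist2(double x, double y, double z,
                               double x0, double y0, double z0,
                               double x1, double y1, double z1) {
  const double vx = x1 - x0, vy = y1 - y0, vz = z1 - z0;
  const double wx = x - x0, wy = y - y0, wz = z - z0;
  const double vv = vx * vx + vy * vy + vz * vz;
  double t = vv > 0 ? (wx * vx + wy * vy + wz * vz) / vv : 0.0;
  if (t < 0) t = 0; else if (t > 1) t = 1;
  const double dx = wx - t * vx, dy = wy - t * vy, dz = wz - t * vz;
  return dx * dx + dy * dy + dz * dz;
}

struct Bins {
  int nb;
  double bs, ox, oy, oz;
  std::vector<std::vector<int> > cells;
  int idx(int bx, int by, int bz) const { return (bz * nb + by) * nb + bx; }
};

// bin primitives; pad = extra margin added to each primitive's AABB
static Bins make_bins(const NumericMatrix &seg, const NumericMatrix &sph,
                      double ox, double oy, double oz, double extent,
                      double pad) {
  Bins B;
  B.nb = std::max(1, (int)std::floor(extent / 0.4));
  if (B.nb > 40) B.nb = 40;
  B.bs = extent / B.nb;
  B.ox = ox; B.oy = oy; B.oz = oz;
  B.cells.assign((size_t)B.nb * B.nb * B.nb, std::vector<int>());
  const int ns = seg.nrow(), np = sph.nrow();
  for (int p = 0; p < ns + np; ++p) {
    double lo[3], hi[3], r;
    if (p < ns) {
      r = seg(p, 6) + pad;
      lo[0] = std::min(seg(p, 0), seg(p, 3)) - r;
      hi[0] = std::max(seg(p, 0), seg(p, 3)) + r;
      lo[1] = std::min(seg(p, 1), seg(p, 4)) - r;
      hi[1] = std::max(seg(p, 1), seg(p, 4)) + r;
      lo[2] = std::min(seg(p, 2), seg(p, 5)) - r;
      hi[2] = std::max(seg(p, 2), seg(p, 5)) + r;
    } else {
      const int q = p - ns;
      r = sph(q, 3) + pad;
      lo[0] = sph(q, 0) - r; hi[0] = sph(q, 0) + r;
      lo[1] = sph(q, 1) - r; hi[1] = sph(q, 1) + r;
      lo[2] = sph(q, 2) - r; hi[2] = sph(q, 2) + r;
    }
    int blo[3], bhi[3];
    const double o[3] = { ox, oy, oz };
    for (int a = 0; a < 3; ++a) {
      blo[a] = std::max(0, (int)std::floor((lo[a] - o[a]) / B.bs));
      bhi[a] = std::min(B.nb - 1, (int)std::floor((hi[a] - o[a]) / B.bs));
    }
    for (int bz = blo[2]; bz <= bhi[2]; ++bz)
      for (int by = blo[1]; by <= bhi[1]; ++by)
        for (int bx = blo[0]; bx <= bhi[0]; ++bx)
          B.cells[B.idx(bx, by, bz)].push_back(p);
  }
  return B;
}

// Fractional occupancy of each voxel of an n^3 grid: fraction of ss^3
// stratified subsample points lying inside the capsule union. seg columns:
// x0 y0 z0 x1 y1 z1 r (cm); sph columns: x y z r (cm).
// [[Rcpp::export]]
NumericVector cpp_occupancy(NumericMatrix seg, NumericMatrix sph, int n,
                            double spacing, NumericVector origin, int ss) {
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double extent = n * spacing;
  const double halfdiag = 0.5 * spacing * std::sqrt(3.0);
  Bins B = make_bins(seg, sph, ox, oy, oz, extent, halfdiag + 1e-9);
  const int ns = seg.nrow();
  NumericVector out((R_xlen_t)n * n * n);
  const int ss3 = ss * ss * ss;
  std::vector<double> offs(ss);
  for (int s = 0; s < ss; ++s) offs[s] = (s + 0.5) / ss * spacing;

  for (int kz = 0; kz < n; ++kz)
    for (int ky = 0; ky < n; ++ky)
      for (int kx = 0; kx < n; ++kx) {
        const double cx = ox + (kx + 0.5) * spacing,
                     cy = oy + (ky + 0.5) * spacing,
                     cz = oz + (kz + 0.5) * spacing;
        int bx = (int)std::floor((cx - ox) / B.bs);
        int by = (int)std::floor((cy - oy) / B.bs);
        int bz = (int)std::floor((cz - oz) / B.bs);
        bx = std::min(std::max(bx, 0), B.nb - 1);
        by = std::min(std::max(by, 0), B.nb - 1);
        bz = std::min(std::max(bz, 0), B.nb - 1);
        const std::vector<int> &cand = B.cells[B.idx(bx, by, bz)];
        const R_xlen_t vi = (R_xlen_t)kz * n * n + (R_xlen_t)ky * n + kx;
        if (cand.empty()) { out[vi] = 0.0; continue; }
        // centre test first: voxels strictly farther than the half diagonal
        // from every surface are uniformly empty / full, no subsampling;
        // otherwise only primitives whose surface can reach the voxel are
        // kept for the subsample loop, nearest first
        bool full = false;
        double dmin = R_PosInf;
        std::vector<std::pair<double, int> > near;
        for (size_t c = 0; c < cand.size() && !full; ++c) {
          const int p = cand[c];
          double d, r;
          if (p < ns) {
            r = seg(p, 6);
            d = std::sqrt(seg_dist2(cx, cy, cz, seg(p, 0), seg(p, 1),
                                    seg(p, 2), seg(p, 3), seg(p, 4),
                                    seg(p, 5)));
          } else {
            const int q = p - ns;
            r = sph(q, 3);
            const double dx = cx - sph(q, 0), dy = cy - sph(q, 1),
                         dz = cz - sph(q, 2);
            d = std::sqrt(dx * dx + dy * dy + dz * dz);
          }
          if (d + halfdiag <= r) full = true;
          if (d - r < dmin) dmin = d - r;
          if (d - r <= halfdiag) near.push_back(std::make_pair(d - r, p));
        }
        if (full) { out[vi] = 1.0; continue; }
        if (dmin > halfdiag) { out[vi] = 0.0; continue; }
        std::sort(near.begin(), near.end());
        const double vx0 = ox + kx * spacing, vy0 = oy + ky * spacing,
                     vz0 = oz + kz * spacing;
        int hits = 0;
        for (int sz = 0; sz < ss; ++sz)
          for (int sy = 0; sy < ss; ++sy)
            for (int sx = 0; sx < ss; ++sx) {
              const double x = vx0 + offs[sx], y = vy0 + offs[sy],
                           z = vz0 + offs[sz];
              bool in = false;
              for (size_t c = 0; c < near.size() && !in; ++c) {
                const int p = near[c].second;
                if (p < ns) {
                  const double r = seg(p, 6);
                  if (seg_dist2(x, y, z, seg(p, 0), seg(p, 1), seg(p, 2),
                                seg(p, 3), seg(p, 4), seg(p, 5)) <= r * r)
                    in = true;
                } else {
                  const int q = p - ns;
                  const double dx = x - sph(q, 0), dy = y - sph(q, 1),
                               dz = z - sph(q, 2), r = sph(q, 3);
                  if (dx * dx + dy * dy + dz * dz <= r * r) in = true;
                }
              }
              if (in) ++hits;
            }
        out[vi] = (double)hits / ss3;
      }
  return out;
}

// Signed distance (distance to capsule-union surface, negative inside) at
// the nodes of an (n+1)^3 lattice. Nodes farther than `far` from every
// binned primitive get the value `far`.
// [[Rcpp::export]]
NumericVector cpp_sdf_grid(NumericMatrix seg, NumericMatrix sph, int n,
                           double spacing, NumericVector origin, double far) {
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double extent = n * spacing;
  Bins B = make_bins(seg, sph, ox, oy, oz, extent, far + 1e-9);
  const int ns = seg.nrow();
  const int m = n + 1;
  NumericVector out((R_xlen_t)m * m * m);
  for (int kz = 0; kz < m; ++kz)
    for (int ky = 0; ky < m; ++ky)
      for (int kx = 0; kx < m; ++kx) {
        const double x = ox + kx * spacing, y = oy + ky * spacing,
                     z = oz + kz * spacing;
        int bx = std::min(std::max((int)std::floor((x - ox) / B.bs), 0), B.nb - 1);
        int by = std::min(std::max((int)std::floor((y - oy) / B.bs), 0), B.nb - 1);
        int bz = std::min(std::max((int)std::floor((z - oz) / B.bs), 0), B.nb - 1);
        const std::vector<int> &cand = B.cells[B.idx(bx, by, bz)];
        double best = far;
        for (size_t c = 0; c < cand.size(); ++c) {
          const int p = cand[c];
          double d;
          if (p < ns) {
            d = std::sqrt(seg_dist2(x, y, z, seg(p, 0), seg(p, 1), seg(p, 2),
                                    seg(p, 3), seg(p, 4), seg(p, 5))) - seg(p, 6);
          } else {
            const int q = p - ns;
            const double dx = x - sph(q, 0), dy = y - sph(q, 1),
                         dz = z - sph(q, 2);
            d = std::sqrt(dx * dx + dy * dy + dz * dz) - sph(q, 3);
          }
          if (d < best) best = d;
        }
        out[(R_xlen_t)kz * m * m + (R_xlen_t)ky * m + kx] = best;
      }
  return out;
}
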