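#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Nearest-generator queries on a uniform grid. Generators are binned once;
// each query scans Chebyshev rings of cells outward and stops as soon as the
// best squared distance cannot be beaten by any farther ring (a point in
// cell c is at least (r-1)*h from every cell in ring r), which for
// near-uniform CVT generator sets terminates after one or two rings.

struct NNGrid {
  int nb;
  double h, ox, oy, oz;
  std::vector<std::vector<int> > cells;
  std::vector<double> cx, cy, cz;

  void build(const NumericMatrix &centers) {
    const int k = centers.nrow();
    cx.resize(k); cy.resize(k); cz.resize(k);
    double lo[3] = { R_PosInf, R_PosInf, R_PosInf },
           hi[3] = { R_NegInf, R_NegInf, R_NegInf };
    for (int j = 0; j < k; ++j) {
      cx[j] = centers(j, 0); cy[j] = centers(j, 1); cz[j] = centers(j, 2);
      const double c[3] = { cx[j], cy[j], cz[j] };
      for (int a = 0; a < 3; ++a) {
        if (c[a] < lo[a]) lo[a] = c[a];
        if (c[a] > hi[a]) hi[a] = c[a];
      }
    }
    const double ext = std::max(std::max(hi[0] - lo[0], hi[1] - lo[1]),
                                hi[2] - lo[2]);
    nb = std::max(1, (int)std::ceil(std::cbrt((double)k)));
    h = (ext > 0 ? ext : 1.0) / nb * 1.000001;
    ox = lo[0]; oy = lo[1]; oz = lo[2];
    cells.assign((size_t)nb * nb * nb, std::vector<int>());
    for (int j = 0; j < k; ++j) {
      const int bx = bin(cx[j] - ox), by = bin(cy[j] - oy), bz = bin(cz[j] - oz);
      cells[(bz * (size_t)nb + by) * nb + bx].push_back(j);
    }
  }
  int bin(double u) const {
    int b = (int)std::floor(u / h);
    if (b < 0) b = 0; if (b >= nb) b = nb - 1;
    return b;
  }
  int query(double x, double y, double z, double &bestd2) const {
    const int bx = bin(x - ox), by = bin(y - oy), bz = bin(z - oz);
    double best = R_PosInf; int bj = -1;
    const int rmax = nb; // worst case scans everything
    for (int r = 0; r <= rmax; ++r) {
      if (bj >= 0 && best <= (double)(r - 1) * (r - 1) * h * h) break;
      const int xlo = std::max(0, bx - r), xhi = std::min(nb - 1, bx + r);
      const int ylo = std::max(0, by - r), yhi = std::min(nb - 1, by + r);
      const int zlo = std::max(0, bz - r), zhi = std::min(nb - 1, bz + r);
      for (int iz = zlo; iz <= zhi; ++iz)
        for (int iy = ylo; iy <= yhi; ++iy)
          for (int ix = xlo; ix <= xhi; ++ix) {
            // ring only: skip interior cells already scanned
            if (r > 0 && std::abs(ix - bx) != r && std::abs(iy - by) != r &&
                std::abs(iz - bz) != r) continue;
            const std::vector<int> &cl = cells[(iz * (size_t)nb + iy) * nb + ix];
            for (size_t t = 0; t < cl.size(); ++t) {
              const int j = cl[t];
              const double dx = x - cx[j], dy = y - cy[j], dz = z - cz[j];
              const double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < best) { best = d2; bj = j; }
            }
          }
    }
    bestd2 = best;
    return bj;
  }
};

// One Lloyd step on a fixed sample cloud: assign every sample to its nearest
// generator, return the per-generator centroids, the assignment cost
// (mean squared distance, i.e. the CVT quantization energy estimate on the
// cloud) and the per-generator sample counts. Generators with no samples
// keep their previous position.
// [[Rcpp::export]]
List cpp_lloyd_step(NumericMatrix samples, NumericMatrix centers) {
  const int n = samples.nrow(), k = centers.nrow();
  NNGrid G; G.build(centers);
  std::vector<double> sx(k, 0.0), sy(k, 0.0), sz(k, 0.0);
  std::vector<int> cnt(k, 0);
  double energy = 0.0;
  for (int i = 0; i < n; ++i) {
    const double x = samples(i, 0), y = samples(i, 1), z = samples(i, 2);
    double d2;
    const int bj = G.query(x, y, z, d2);
    energy += d2;
    sx[bj] += x; sy[bj] += y; sz[bj] += z; cnt[bj]++;
  }
  NumericMatrix out(k, 3);
  IntegerVector counts(k);
  for (int j = 0; j < k; ++j) {
    if (cnt[j] > 0) {
      out(j, 0) = sx[j] / cnt[j];
      out(j, 1) = sy[j] / cnt[j];
      out(j, 2) = sz[j] / cnt[j];
    } else {
      out(j, 0) = centers(j, 0); out(j, 1) = centers(j, 1);
      out(j, 2) = centers(j, 2);
    }
    counts[j] = cnt[j];
  }
  return List::create(_["centers"] = out,
                      _["energy"] = energy / n,
                      _["counts"] = counts);
}

// Nearest-generator index (1-based) for each sample; used by the energy
// oracle and by tests.
// [[Rcpp::export]]
IntegerVector cpp_nearest_index(NumericMatrix samples, NumericMatrix centers) {
  const int n = samples.nrow();
  NNGrid G; G.build(centers);
  IntegerVector idx(n);
  for (int i = 0; i < n; ++i) {
    double d2;
    idx[i] = G.query(samples(i, 0), samples(i, 1), samples(i, 2), d2) + 1;
  }
  return idx;
}
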