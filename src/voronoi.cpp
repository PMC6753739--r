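#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Clipped 3D Voronoi diagram by per-cell vertex enumeration.
//
// For each generator i the cell (intersection of bisector half-spaces with
// the cube) is reconstructed by solving all triples of candidate planes
// (bisectors towards the k nearest neighbours plus the six cube faces),
// keeping solutions that satisfy every candidate half-space and that are
// globally closest to generator i among ALL generators. Cell edges are the
// vertex pairs sharing two active planes. kNN pruning only limits which
// planes can form vertices; the global closest-generator test makes false
// vertices impossible, so k merely has to exceed the true neighbour count
// of the cell (generous for near-uniform CVT point sets).

struct Plane { double nx, ny, nz, d; int bis; }; // n.x <= d ; bis: 1 = bisector

struct Vert {
  double x, y, z;
  std::vector<int> active;
};

// [[Rcpp::export]]
NumericMatrix cpp_voronoi_cell_edges(NumericMatrix pts, double cube_edge,
                                     int k_neighbors) {
  const int n = pts.nrow();
  const double tol_sat = 1e-9, tol_act = 1e-7, tol_merge = 1e-8;
  std::vector<double> px(n), py(n), pz(n);
  for (int i = 0; i < n; ++i) {
    px[i] = pts(i, 0); py[i] = pts(i, 1); pz[i] = pts(i, 2);
  }
  std::vector<double> rows; // x0 y0 z0 x1 y1 z1 nbis cell

  for (int i = 0; i < n; ++i) {
    // k nearest neighbours of i
    std::vector<std::pair<double, int> > dist;
    dist.reserve(n - 1);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = px[j] - px[i], dy = py[j] - py[i], dz = pz[j] - pz[i];
      dist.push_back(std::make_pair(dx * dx + dy * dy + dz * dz, j));
    }
    const int k = std::min((int)dist.size(), k_neighbors);
    std::partial_sort(dist.begin(), dist.begin() + k, dist.end());

    std::vector<Plane> pl;
    for (int m = 0; m < k; ++m) {
      const int j = dist[m].second;
      double nx = px[j] - px[i], ny = py[j] - py[i], nz = pz[j] - pz[i];
      const double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
      nx /= nn; ny /= nn; nz /= nn;
      const double mx = 0.5 * (px[i] + px[j]), my = 0.5 * (py[i] + py[j]),
                   mz = 0.5 * (pz[i] + pz[j]);
      Plane p = { nx, ny, nz, nx * mx + ny * my + nz * mz, 1 };
      pl.push_back(p);
    }
    // cube faces: -x<=0, x<=L etc.
    const double L = cube_edge;
    Plane f1 = { -1, 0, 0, 0, 0 }; pl.push_back(f1);
    Plane f2 = {  1, 0, 0, L, 0 }; pl.push_back(f2);
    Plane f3 = { 0, -1, 0, 0, 0 }; pl.push_back(f3);
    Plane f4 = { 0,  1, 0, L, 0 }; pl.push_back(f4);
    Plane f5 = { 0, 0, -1, 0, 0 }; pl.push_back(f5);
    Plane f6 = { 0, 0,  1, L, 0 }; pl.push_back(f6);
    const int np = (int)pl.size();

    std::vector<Vert> verts;
    for (int a = 0; a < np; ++a)
      for (int b = a + 1; b < np; ++b)
        for (int c = b + 1; c < np; ++c) {
          const Plane &A = pl[a], &B = pl[b], &C = pl[c];
          const double det =
            A.nx * (B.ny * C.nz - B.nz * C.ny) -
            A.ny * (B.nx * C.nz - B.nz * C.nx) +
            A.nz * (B.nx * C.ny - B.ny * C.nx);
          if (std::fabs(det) < 1e-10) continue;
          const double x = (A.d * (B.ny * C.nz - B.nz * C.ny) -
                            A.ny * (B.d * C.nz - B.nz * C.d) +
                            A.nz * (B.d * C.ny - B.ny * C.d)) / det;
          const double y = (A.nx * (B.d * C.nz - B.nz * C.d) -
                            A.d * (B.nx * C.nz - B.nz * C.nx) +
                            A.nz * (B.nx * C.d - B.d * C.nx)) / det;
          const double z = (A.nx * (B.ny * C.d - B.d * C.ny) -
                            A.ny * (B.nx * C.d - B.d * C.nx) +
                            A.d * (B.nx * C.ny - B.ny * C.nx)) / det;
          // satisfy all candidate half-spaces
          bool ok = true;
          for (int q = 0; q < np && ok; ++q) {
            if (pl[q].nx * x + pl[q].ny * y + pl[q].nz * z > pl[q].d + tol_sat)
              ok = false;
          }
          if (!ok) continue;
          // globally closest to generator i
          const double dxi = x - px[i], dyi = y - py[i], dzi = z - pz[i];
          const double di = dxi * dxi + dyi * dyi + dzi * dzi;
          for (int j = 0; j < n && ok; ++j) {
            if (j == i) continue;
            const double dx = x - px[j], dy = y - py[j], dz = z - pz[j];
            if (dx * dx + dy * dy + dz * dz < di - 1e-12) ok = false;
          }
          if (!ok) continue;
          // merge with existing vertex or add
          int hit = -1;
          for (size_t v = 0; v < verts.size(); ++v) {
            const double dx = verts[v].x - x, dy = verts[v].y - y,
                         dz = verts[v].z - z;
            if (dx * dx + dy * dy + dz * dz < tol_merge * tol_merge) {
              hit = (int)v; break;
            }
          }
          if (hit < 0) {
            Vert v; v.x = x; v.y = y; v.z = z;
            verts.push_back(v); hit = (int)verts.size() - 1;
          }
          // active planes of this vertex
          for (int q = 0; q < np; ++q) {
            const double r = pl[q].nx * verts[hit].x + pl[q].ny * verts[hit].y +
                             pl[q].nz * verts[hit].z - pl[q].d;
            if (std::fabs(r) < tol_act) {
              std::vector<int> &ac = verts[hit].active;
              if (std::find(ac.begin(), ac.end(), q) == ac.end())
                ac.push_back(q);
            }
          }
        }

    // edges: vertex pairs sharing two planes
    const int nv = (int)verts.size();
    for (int a = 0; a < np; ++a)
      for (int b = a + 1; b < np; ++b) {
        std::vector<int> on;
        for (int v = 0; v < nv; ++v) {
          const std::vector<int> &ac = verts[v].active;
          if (std::find(ac.begin(), ac.end(), a) != ac.end() &&
              std::find(ac.begin(), ac.end(), b) != ac.end())
            on.push_back(v);
        }
        if ((int)on.size() < 2) continue;
        int v0 = on[0], v1 = on[1];
        if ((int)on.size() > 2) {
          // collinear set: take extremes along the line
          double dirx = 0, diry = 0, dirz = 0;
          for (size_t t = 1; t < on.size(); ++t) {
            dirx = verts[on[t]].x - verts[on[0]].x;
            diry = verts[on[t]].y - verts[on[0]].y;
            dirz = verts[on[t]].z - verts[on[0]].z;
            if (dirx * dirx + diry * diry + dirz * dirz > 1e-16) break;
          }
          double lo = R_PosInf, hi = R_NegInf;
          for (size_t t = 0; t < on.size(); ++t) {
            const double s = verts[on[t]].x * dirx + verts[on[t]].y * diry +
                             verts[on[t]].z * dirz;
            if (s < lo) { lo = s; v0 = on[t]; }
            if (s > hi) { hi = s; v1 = on[t]; }
          }
        }
        const double ex = verts[v1].x - verts[v0].x,
                     ey = verts[v1].y - verts[v0].y,
                     ez = verts[v1].z - verts[v0].z;
        if (ex * ex + ey * ey + ez * ez < 1e-16) continue;
        const int nbis = pl[a].bis + pl[b].bis;
        rows.push_back(verts[v0].x); rows.push_back(verts[v0].y);
        rows.push_back(verts[v0].z);
        rows.push_back(verts[v1].x); rows.push_back(verts[v1].y);
        rows.push_back(verts[v1].z);
        rows.push_back((double)nbis); rows.push_back((double)(i + 1));
      }
  }

  const int ne = (int)rows.size() / 8;
  NumericMatrix out(ne, 8);
  for (int e = 0; e < ne; ++e)
    for (int c = 0; c < 8; ++c) out(e, c) = rows[e * 8 + c];
  colnames(out) = CharacterVector::create("x0", "y0", "z0", "x1", "y1", "z1",
                                          "nbis", "cell");
  return out;
}
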