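#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>
#include <algorithm>
using namespace Rcpp;

// Marching tetrahedra over a node-sampled scalar field (negative = inside).
// Each lattice cube is split into the six Kuhn tetrahedra sharing the main
// diagonal; the split is identical in every cube, so faces between
// neighbouring cubes are conforming and the extracted surface is watertight
// up to the lattice boundary. Iso-surface vertices live on lattice edges and
// are deduplicated by edge key, which makes the triangle mesh vertex-shared.

struct MeshAcc {
  std::map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;
  const double *f;
  int m;                 // nodes per axis
  double ox, oy, oz, h;  // origin and node spacing

  void node_pos(uint64_t id, double &x, double &y, double &z) const {
    const int kx = (int)(id % m), ky = (int)((id / m) % m),
              kz = (int)(id / ((uint64_t)m * m));
    x = ox + kx * h; y = oy + ky * h; z = oz + kz * h;
  }
  int cut(uint64_t a, uint64_t b) {
    if (a > b) std::swap(a, b);
    const uint64_t key = a * ((uint64_t)m * m * m) + b;
    std::map<uint64_t, int>::iterator it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    const double fa = f[a], fb = f[b];
    double t = fa / (fa - fb);
    if (t < 0) t = 0; else if (t > 1) t = 1;
    double ax, ay, az, bx, by, bz;
    node_pos(a, ax, ay, az); node_pos(b, bx, by, bz);
    vx.push_back(ax + t * (bx - ax));
    vy.push_back(ay + t * (by - ay));
    vz.push_back(az + t * (bz - az));
    const int id = (int)vx.size() - 1;
    edge_vertex[key] = id;
    return id;
  }
  void emit(int a, int b, int c,
            double rx, double ry, double rz) { // r: inside -> outside ref
    const double ux = vx[b] - vx[a], uy = vy[b] - vy[a], uz = vz[b] - vz[a];
    const double wx = vx[c] - vx[a], wy = vy[c] - vy[a], wz = vz[c] - vz[a];
    const double nx = uy * wz - uz * wy, ny = uz * wx - ux * wz,
                 nz = ux * wy - uy * wx;
    if (nx * rx + ny * ry + nz * rz < 0) std::swap(b, c);
    tri.push_back(a); tri.push_back(b); tri.push_back(c);
  }
  void tet(uint64_t v0, uint64_t v1, uint64_t v2, uint64_t v3) {
    const uint64_t v[4] = { v0, v1, v2, v3 };
    int in[4], nin = 0, out[4], nout = 0;
    for (int q = 0; q < 4; ++q) {
      if (f[v[q]] < 0) in[nin++] = q; else out[nout++] = q;
    }
    if (nin == 0 || nin == 4) return;
    double cix = 0, ciy = 0, ciz = 0, cox = 0, coy = 0, coz = 0, x, y, z;
    for (int q = 0; q < nin; ++q) {
      node_pos(v[in[q]], x, y, z); cix += x / nin; ciy += y / nin; ciz += z / nin;
    }
    for (int q = 0; q < nout; ++q) {
      node_pos(v[out[q]], x, y, z); cox += x / nout; coy += y / nout; coz += z / nout;
    }
    const double rx = cox - cix, ry = coy - ciy, rz = coz - ciz;
    if (nin == 1) {
      const int A = in[0];
      emit(cut(v[A], v[out[0]]), cut(v[A], v[out[1]]), cut(v[A], v[out[2]]),
           rx, ry, rz);
    } else if (nin == 3) {
      const int A = out[0];
      emit(cut(v[A], v[in[0]]), cut(v[A], v[in[1]]), cut(v[A], v[in[2]]),
           rx, ry, rz);
    } else { // 2 in, 2 out: quad
      const int A = in[0], B = in[1], C = out[0], D = out[1];
      const int pAC = cut(v[A], v[C]), pAD = cut(v[A], v[D]),
                pBC = cut(v[B], v[C]), pBD = cut(v[B], v[D]);
      emit(pAC, pAD, pBD, rx, ry, rz);
      emit(pAC, pBD, pBC, rx, ry, rz);
    }
  }
};

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector values, int n, double spacing,
                       NumericVector origin) {
  const int m = n + 1;
  if ((R_xlen_t)m * m * m != values.size())
    stop("values must hold (n+1)^3 node samples");
  MeshAcc M;
  M.f = REAL(values); M.m = m; M.h = spacing;
  M.ox = origin[0]; M.oy = origin[1]; M.oz = origin[2];
  const uint64_t sx = 1, sy = m, sz = (uint64_t)m * m;
  static const int perms[6][3] = {
    {0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}
  };
  const uint64_t step[3] = { sx, sy, sz };
  for (int kz = 0; kz < n; ++kz)
    for (int ky = 0; ky < n; ++ky)
      for (int kx = 0; kx < n; ++kx) {
        const uint64_t base = kx * sx + ky * sy + kz * sz;
        for (int p = 0; p < 6; ++p) {
          const uint64_t a = base;
          const uint64_t b = a + step[perms[p][0]];
          const uint64_t c = b + step[perms[p][1]];
          const uint64_t d = c + step[perms[p][2]];
          M.tet(a, b, c, d);
        }
      }
  const int nv = (int)M.vx.size(), nt = (int)M.tri.size() / 3;
  NumericMatrix V(nv, 3);
  for (int i = 0; i < nv; ++i) {
    V(i, 0) = M.vx[i]; V(i, 1) = M.vy[i]; V(i, 2) = M.vz[i];
  }
  IntegerMatrix F(nt, 3);
  for (int i = 0; i < nt; ++i) {
    F(i, 0) = M.tri[3 * i] + 1;
    F(i, 1) = M.tri[3 * i + 1] + 1;
    F(i, 2) = M.tri[3 * i + 2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
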