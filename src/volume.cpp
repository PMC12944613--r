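// Volumetric primitives for CT outer-shell extraction: exact Euclidean
// distance transform (Felzenszwalb & Huttenlocher, separable), 6-connected
// background propagation, truncated-Gaussian smoothing, and isosurface
// extraction on a consistent 6-tetrahedron cube decomposition with
// shared-edge vertex welding.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <limits>
#include <queue>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

// Large finite stand-in for "no site on this scan line": keeps the
// lower-envelope intersections finite (INF - INF would be NaN).
const double INF = 1e15;

// 1D squared distance transform of a sampled function f (Felzenszwalb)
void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
          std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// 3D squared EDT to the set of true voxels (result 0 on the set)
void edt3d(std::vector<double>& g, int nx, int ny, int nz) {
  int nmax = std::max({nx, ny, nz});
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1);
  // along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      size_t base = (size_t)k * nx * ny + (size_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, d, nx, v, z);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = g[base + (size_t)j * nx];
      dt1d(f, d, ny, v, z);
      for (int j = 0; j < ny; ++j) g[base + (size_t)j * nx] = d[j];
    }
  // along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      size_t base = (size_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = g[base + (size_t)k * nx * ny];
      dt1d(f, d, nz, v, z);
      for (int k = 0; k < nz; ++k) g[base + (size_t)k * nx * ny] = d[k];
    }
}

}  // namespace

// Signed distance field in mm: negative inside (solid), positive outside.
// Distances are exact Euclidean between voxel centers.
// [[Rcpp::export]]
NumericVector cpp_signed_distance_field(LogicalVector solid, IntegerVector dims,
                                        double spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<double> dOut(n), dIn(n);
  for (size_t i = 0; i < n; ++i) {
    dOut[i] = solid[i] ? 0.0 : INF;   // distance to foreground
    dIn[i] = solid[i] ? INF : 0.0;    // distance to background
  }
  edt3d(dOut, nx, ny, nz);
  edt3d(dIn, nx, ny, nz);
  NumericVector out((R_xlen_t)n);
  for (size_t i = 0; i < n; ++i)
    out[i] = solid[i] ? -spacing * std::sqrt(dIn[i]) : spacing * std::sqrt(dOut[i]);
  return out;
}

// Background propagation: background voxels 6-connected to a seeded face stay
// background, all other background voxels (internal cavities) become solid.
// seedFaces: logical length 6 (x0, x1, y0, y1, z0, z1).
// [[Rcpp::export]]
LogicalVector cpp_fill_outer_shell(LogicalVector fg, IntegerVector dims,
                                   LogicalVector seedFaces) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<uint8_t> reached(n, 0);
  std::queue<size_t> q;
  auto push = [&](int i, int j, int k) {
    size_t id = (size_t)k * nx * ny + (size_t)j * nx + i;
    if (!fg[id] && !reached[id]) { reached[id] = 1; q.push(id); }
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      if (seedFaces[0]) push(0, j, k);
      if (seedFaces[1]) push(nx - 1, j, k);
    }
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      if (seedFaces[2]) push(i, 0, k);
      if (seedFaces[3]) push(i, ny - 1, k);
    }
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      if (seedFaces[4]) push(i, j, 0);
      if (seedFaces[5]) push(i, j, nz - 1);
    }
  while (!q.empty()) {
    size_t id = q.front(); q.pop();
    int i = id % nx, j = (id / nx) % ny, k = id / ((size_t)nx * ny);
    if (i > 0) push(i - 1, j, k);
    if (i < nx - 1) push(i + 1, j, k);
    if (j > 0) push(i, j - 1, k);
    if (j < ny - 1) push(i, j + 1, k);
    if (k > 0) push(i, j, k - 1);
    if (k < nz - 1) push(i, j, k + 1);
  }
  LogicalVector out((R_xlen_t)n);
  for (size_t i = 0; i < n; ++i) out[i] = fg[i] || !reached[i];
  return out;
}

// Separable truncated Gaussian (radius = ceil(3 sigma)), kernel renormalized
// at array borders. sigma in voxel units; sigma <= 0 is identity.
// [[Rcpp::export]]
NumericVector cpp_gaussian3d(NumericVector field, IntegerVector dims, double sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  if (sigma <= 0) return clone(field);
  int r = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * r + 1);
  for (int i = -r; i <= r; ++i) ker[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
  std::vector<double> a(field.begin(), field.end()), b(n);
  auto pass = [&](int len, size_t stride, size_t nLines, auto lineBase) {
    for (size_t L = 0; L < nLines; ++L) {
      size_t base = lineBase(L);
      for (int p = 0; p < len; ++p) {
        double s = 0, wsum = 0;
        int lo = std::max(0, p - r), hi = std::min(len - 1, p + r);
        for (int t = lo; t <= hi; ++t) {
          double w = ker[t - p + r];
          s += w * a[base + (size_t)t * stride];
          wsum += w;
        }
        b[base + (size_t)p * stride] = s / wsum;
      }
    }
    std::swap(a, b);
  };
  pass(nx, 1, (size_t)ny * nz, [&](size_t L) { return L * (size_t)nx; });
  pass(ny, (size_t)nx, (size_t)nx * nz, [&](size_t L) {
    size_t k = L / nx, i = L % nx;
    return k * (size_t)nx * ny + i;
  });
  pass(nz, (size_t)nx * ny, (size_t)nx * ny, [&](size_t L) { return L; });
  NumericVector out((R_xlen_t)n);
  std::copy(a.begin(), a.end(), out.begin());
  return out;
}

namespace {

// 6-tetrahedron decomposition around the main diagonal v0-v7, with cube
// corner numbering v = x + 2 y + 4 z. Shared cube-face diagonals are
// consistent between neighbouring cells, so the extracted surface is
// watertight by construction.
const int TETS[6][4] = {
    {0, 1, 3, 7}, {0, 2, 3, 7}, {0, 2, 6, 7},
    {0, 4, 6, 7}, {0, 4, 5, 7}, {0, 1, 5, 7}};
const int CORNER_OFF[8][3] = {
    {0, 0, 0}, {1, 0, 0}, {0, 1, 0}, {1, 1, 0},
    {0, 0, 1}, {1, 0, 1}, {0, 1, 1}, {1, 1, 1}};

struct MeshBuilder {
  std::vector<double> vx, vy, vz;
  std::vector<int> tri;  // 0-based, flat
  std::unordered_map<uint64_t, int> edgeVert;

  int edgePoint(size_t gi, size_t gj, double fi, double fj,
                const double* pi, const double* pj) {
    uint64_t a = gi, b = gj;
    if (a > b) { std::swap(a, b); std::swap(fi, fj); std::swap(pi, pj); }
    uint64_t key = (a << 32) | b;
    auto it = edgeVert.find(key);
    if (it != edgeVert.end()) return it->second;
    double t = fi / (fi - fj);  // zero crossing (fi, fj opposite signs)
    int id = (int)vx.size();
    vx.push_back(pi[0] + t * (pj[0] - pi[0]));
    vy.push_back(pi[1] + t * (pj[1] - pi[1]));
    vz.push_back(pi[2] + t * (pj[2] - pi[2]));
    edgeVert[key] = id;
    return id;
  }

  void addTri(int a, int b, int c, const double* posAvg, const double* negAvg) {
    // orient so the normal points from the negative (inside) toward the
    // positive (outside) side
    double ux = vx[b] - vx[a], uy = vy[b] - vy[a], uz = vz[b] - vz[a];
    double wx = vx[c] - vx[a], wy = vy[c] - vy[a], wz = vz[c] - vz[a];
    double nxx = uy * wz - uz * wy, nyy = uz * wx - ux * wz, nzz = ux * wy - uy * wx;
    double dx = posAvg[0] - negAvg[0], dy = posAvg[1] - negAvg[1], dz = posAvg[2] - negAvg[2];
    if (nxx * dx + nyy * dy + nzz * dz < 0) std::swap(b, c);
    tri.push_back(a); tri.push_back(b); tri.push_back(c);
  }
};

}  // namespace

// Isosurface of `field` at level 0 (negative = inside), on cells whose
// z cell-index lies in [zlo, zhi) (0-based; pass 0 and nz-1 for all).
// Vertices are welded through shared-edge keys. Returns V (mm) and F (1-based).
// [[Rcpp::export]]
List cpp_isosurface(NumericVector field, IntegerVector dims, double spacing,
                    NumericVector origin, int zlo, int zhi) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  MeshBuilder mb;
  double cornerPos[8][3];
  double f[8];
  size_t gid[8];
  for (int k = zlo; k < std::min(zhi, nz - 1); ++k) {
    for (int j = 0; j < ny - 1; ++j) {
      for (int i = 0; i < nx - 1; ++i) {
        bool anyNeg = false, anyPos = false;
        for (int c = 0; c < 8; ++c) {
          int ci = i + CORNER_OFF[c][0], cj = j + CORNER_OFF[c][1], ck = k + CORNER_OFF[c][2];
          size_t id = (size_t)ck * nx * ny + (size_t)cj * nx + ci;
          gid[c] = id;
          f[c] = field[id];
          if (f[c] == 0) f[c] = 1e-30;  // push exact zeros outside
          (f[c] < 0 ? anyNeg : anyPos) = true;
          cornerPos[c][0] = origin[0] + ci * spacing;
          cornerPos[c][1] = origin[1] + cj * spacing;
          cornerPos[c][2] = origin[2] + ck * spacing;
        }
        if (!anyNeg || !anyPos) continue;
        for (int t = 0; t < 6; ++t) {
          const int* T = TETS[t];
          int neg[4], pos[4], nNeg = 0, nPos = 0;
          for (int c = 0; c < 4; ++c)
            (f[T[c]] < 0 ? neg[nNeg++] : pos[nPos++]) = T[c];
          if (nNeg == 0 || nNeg == 4) continue;
          double posAvg[3] = {0, 0, 0}, negAvg[3] = {0, 0, 0};
          for (int c = 0; c < nPos; ++c)
            for (int d = 0; d < 3; ++d) posAvg[d] += cornerPos[pos[c]][d] / nPos;
          for (int c = 0; c < nNeg; ++c)
            for (int d = 0; d < 3; ++d) negAvg[d] += cornerPos[neg[c]][d] / nNeg;
          if (nNeg == 1 || nNeg == 3) {
            int apex = (nNeg == 1) ? neg[0] : pos[0];
            const int* others = (nNeg == 1) ? pos : neg;
            int e0 = mb.edgePoint(gid[apex], gid[others[0]], f[apex], f[others[0]],
                                  cornerPos[apex], cornerPos[others[0]]);
            int e1 = mb.edgePoint(gid[apex], gid[others[1]], f[apex], f[others[1]],
                                  cornerPos[apex], cornerPos[others[1]]);
            int e2 = mb.edgePoint(gid[apex], gid[others[2]], f[apex], f[others[2]],
                                  cornerPos[apex], cornerPos[others[2]]);
            mb.addTri(e0, e1, e2, posAvg, negAvg);
          } else {
            // 2-2: quad from the four crossing edges
            int e00 = mb.edgePoint(gid[neg[0]], gid[pos[0]], f[neg[0]], f[pos[0]],
                                   cornerPos[neg[0]], cornerPos[pos[0]]);
            int e01 = mb.edgePoint(gid[neg[0]], gid[pos[1]], f[neg[0]], f[pos[1]],
                                   cornerPos[neg[0]], cornerPos[pos[1]]);
            int e11 = mb.edgePoint(gid[neg[1]], gid[pos[1]], f[neg[1]], f[pos[1]],
                                   cornerPos[neg[1]], cornerPos[pos[1]]);
            int e10 = mb.edgePoint(gid[neg[1]], gid[pos[0]], f[neg[1]], f[pos[0]],
                                   cornerPos[neg[1]], cornerPos[pos[0]]);
            mb.addTri(e00, e01, e11, posAvg, negAvg);
            mb.addTri(e00, e11, e10, posAvg, negAvg);
          }
        }
      }
    }
  }
  int nVert = (int)mb.vx.size(), nTri = (int)mb.tri.size() / 3;
  NumericMatrix V(nVert, 3);
  for (int i = 0; i < nVert; ++i) {
    V(i, 0) = mb.vx[i]; V(i, 1) = mb.vy[i]; V(i, 2) = mb.vz[i];
  }
  IntegerMatrix F(nTri, 3);
  for (int t = 0; t < nTri; ++t)
    for (int c = 0; c < 3; ++c) F(t, c) = mb.tri[3 * t + c] + 1;
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Merge vertices closer than tol (grid hash on quantized coordinates) and
// drop faces that become degenerate. Faces 1-based in and out.
// [[Rcpp::export]]
List cpp_weld_vertices(NumericMatrix V, IntegerMatrix F, double tol) {
  int nV = V.nrow(), nF = F.nrow();
  std::vector<int> remap(nV, -1);
  std::vector<int> keep;
  if (tol <= 0) tol = 1e-12;
  std::unordered_map<uint64_t, std::vector<int>> grid;
  auto key = [&](long long a, long long b, long long c) {
    uint64_t h = 1469598103934665603ull;
    for (long long v : {a, b, c}) {
      h ^= (uint64_t)v;
      h *= 1099511628211ull;
    }
    return h;
  };
  for (int i = 0; i < nV; ++i) {
    long long qx = (long long)std::floor(V(i, 0) / tol);
    long long qy = (long long)std::floor(V(i, 1) / tol);
    long long qz = (long long)std::floor(V(i, 2) / tol);
    int found = -1;
    for (long long dx = -1; dx <= 1 && found < 0; ++dx)
      for (long long dy = -1; dy <= 1 && found < 0; ++dy)
        for (long long dz = -1; dz <= 1 && found < 0; ++dz) {
          auto it = grid.find(key(qx + dx, qy + dy, qz + dz));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            double ddx = V(i, 0) - V(keep[j], 0);
            double ddy = V(i, 1) - V(keep[j], 1);
            double ddz = V(i, 2) - V(keep[j], 2);
            if (ddx * ddx + ddy * ddy + ddz * ddz <= tol * tol) { found = j; break; }
          }
        }
    if (found >= 0) {
      remap[i] = found;
    } else {
      remap[i] = (int)keep.size();
      grid[key(qx, qy, qz)].push_back((int)keep.size());
      keep.push_back(i);
    }
  }
  NumericMatrix V2((int)keep.size(), 3);
  for (size_t i = 0; i < keep.size(); ++i)
    for (int d = 0; d < 3; ++d) V2(i, d) = V(keep[i], d);
  std::vector<int> fa, fb, fc;
  for (int t = 0; t < nF; ++t) {
    int a = remap[F(t, 0) - 1], b = remap[F(t, 1) - 1], c = remap[F(t, 2) - 1];
    if (a == b || b == c || a == c) continue;
    fa.push_back(a + 1); fb.push_back(b + 1); fc.push_back(c + 1);
  }
  IntegerMatrix F2((int)fa.size(), 3);
  for (size_t t = 0; t < fa.size(); ++t) {
    F2(t, 0) = fa[t]; F2(t, 1) = fb[t]; F2(t, 2) = fc[t];
  }
  return List::create(_["vertices"] = V2, _["faces"] = F2);
}
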