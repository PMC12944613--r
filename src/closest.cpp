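// Triangle-mesh proximity queries: uniform-grid accelerated closest point,
// angle-weighted pseudonormal signing, interpolated surface normals.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <limits>
#include <algorithm>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};
inline Vec3 v3(double x, double y, double z) { return {x, y, z}; }
inline Vec3 operator-(const Vec3& a, const Vec3& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec3 operator+(const Vec3& a, const Vec3& b) { return {a.x + b.x, a.y + b.y, a.z + b.z}; }
inline Vec3 operator*(double s, const Vec3& a) { return {s * a.x, s * a.y, s * a.z}; }
inline double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }
inline Vec3 normalize(const Vec3& a) {
  double n = norm(a);
  return n > 0 ? (1.0 / n) * a : a;
}

// Ericson, Real-Time Collision Detection: closest point on triangle abc to p.
// region: 0 face interior, 1/2/3 vertex a/b/c, 4 edge ab, 5 edge bc, 6 edge ca
Vec3 closestPtTriangle(const Vec3& p, const Vec3& a, const Vec3& b, const Vec3& c,
                       int& region) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) { region = 1; return a; }
  Vec3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) { region = 2; return b; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    region = 4; return a + v * ab;
  }
  Vec3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) { region = 3; return c; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    region = 6; return a + w * ac;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    region = 5; return b + w * (c - b);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  region = 0;
  return a + v * ab + w * ac;
}

struct TriGrid {
  double ox, oy, oz;   // grid origin
  double cell;         // cell size
  int nx, ny, nz;
  std::vector<std::vector<int>> bins;  // triangle indices per cell
  std::vector<double> tv;              // flattened triangle vertices, 9 per tri

  inline int clampi(int v, int hi) const { return v < 0 ? 0 : (v >= hi ? hi - 1 : v); }
  inline int idx(int i, int j, int k) const { return (k * ny + j) * nx + i; }
};

void buildGrid(const NumericMatrix& V, const IntegerMatrix& F, TriGrid& g) {
  int nT = F.nrow();
  g.tv.resize((size_t)nT * 9);
  for (int t = 0; t < nT; ++t)
    for (int c = 0; c < 3; ++c) {
      int vi = F(t, c) - 1;
      g.tv[(size_t)t * 9 + 3 * c] = V(vi, 0);
      g.tv[(size_t)t * 9 + 3 * c + 1] = V(vi, 1);
      g.tv[(size_t)t * 9 + 3 * c + 2] = V(vi, 2);
    }
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < V.nrow(); ++i)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], V(i, d));
      hi[d] = std::max(hi[d], V(i, d));
    }
  double ext = std::max({hi[0] - lo[0], hi[1] - lo[1], hi[2] - lo[2], 1e-9});
  // aim for ~ (#tri)^(1/3) cells per axis, clamped
  int target = std::max(1, std::min(96, 2 * (int)std::ceil(std::cbrt((double)nT))));
  g.cell = ext / target;
  for (int d = 0; d < 3; ++d) lo[d] -= 0.5 * g.cell;
  g.ox = lo[0]; g.oy = lo[1]; g.oz = lo[2];
  g.nx = std::max(1, (int)std::ceil((hi[0] - lo[0]) / g.cell) + 1);
  g.ny = std::max(1, (int)std::ceil((hi[1] - lo[1]) / g.cell) + 1);
  g.nz = std::max(1, (int)std::ceil((hi[2] - lo[2]) / g.cell) + 1);
  g.bins.assign((size_t)g.nx * g.ny * g.nz, {});
  for (int t = 0; t < nT; ++t) {
    double tlo[3] = {R_PosInf, R_PosInf, R_PosInf};
    double thi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int c = 0; c < 3; ++c) {
      int vi = F(t, c) - 1;
      double p[3] = {V(vi, 0), V(vi, 1), V(vi, 2)};
      for (int d = 0; d < 3; ++d) {
        tlo[d] = std::min(tlo[d], p[d]);
        thi[d] = std::max(thi[d], p[d]);
      }
    }
    int i0 = g.clampi((int)((tlo[0] - g.ox) / g.cell), g.nx);
    int i1 = g.clampi((int)((thi[0] - g.ox) / g.cell), g.nx);
    int j0 = g.clampi((int)((tlo[1] - g.oy) / g.cell), g.ny);
    int j1 = g.clampi((int)((thi[1] - g.oy) / g.cell), g.ny);
    int k0 = g.clampi((int)((tlo[2] - g.oz) / g.cell), g.nz);
    int k1 = g.clampi((int)((thi[2] - g.oz) / g.cell), g.nz);
    for (int k = k0; k <= k1; ++k)
      for (int j = j0; j <= j1; ++j)
        for (int i = i0; i <= i1; ++i) g.bins[g.idx(i, j, k)].push_back(t);
  }
}

// closest triangle to p via expanding ring search
void queryGrid(const TriGrid& g, const NumericMatrix& V, const IntegerMatrix& F,
               const Vec3& p, double& bestD2, int& bestT, Vec3& bestC, int& bestRegion) {
  bestD2 = std::numeric_limits<double>::infinity();
  bestT = -1; bestRegion = 0;
  int ci = g.clampi((int)((p.x - g.ox) / g.cell), g.nx);
  int cj = g.clampi((int)((p.y - g.oy) / g.cell), g.ny);
  int ck = g.clampi((int)((p.z - g.oz) / g.cell), g.nz);
  int maxRing = std::max({g.nx, g.ny, g.nz});
  for (int ring = 0; ring <= maxRing; ++ring) {
    // if already found something, can we stop? any cell at this ring is at
    // least (ring-1)*cell away from p
    if (bestT >= 0) {
      double minPossible = (ring - 1) * g.cell;
      if (minPossible > 0 && minPossible * minPossible > bestD2) break;
    }
    bool any = false;
    int i0 = ci - ring, i1 = ci + ring;
    int j0 = cj - ring, j1 = cj + ring;
    int k0 = ck - ring, k1 = ck + ring;
    for (int k = k0; k <= k1; ++k) {
      if (k < 0 || k >= g.nz) continue;
      for (int j = j0; j <= j1; ++j) {
        if (j < 0 || j >= g.ny) continue;
        for (int i = i0; i <= i1; ++i) {
          if (i < 0 || i >= g.nx) continue;
          // only the shell of the ring
          if (ring > 0 && i != i0 && i != i1 && j != j0 && j != j1 && k != k0 && k != k1)
            continue;
          any = true;
          const std::vector<int>& bin = g.bins[g.idx(i, j, k)];
          for (int t : bin) {
            const double* tp = &g.tv[(size_t)t * 9];
            Vec3 a = v3(tp[0], tp[1], tp[2]);
            Vec3 b = v3(tp[3], tp[4], tp[5]);
            Vec3 c = v3(tp[6], tp[7], tp[8]);
            int region;
            Vec3 q = closestPtTriangle(p, a, b, c, region);
            Vec3 d = p - q;
            double d2 = dot(d, d);
            if (d2 < bestD2) {
              bestD2 = d2; bestT = t; bestC = q; bestRegion = region;
            }
          }
        }
      }
    }
    if (!any && bestT >= 0) break;
  }
}

inline uint64_t edgeKey(int a, int b) {
  if (a > b) std::swap(a, b);
  return ((uint64_t)(uint32_t)a << 32) | (uint32_t)b;
}

}  // namespace

// Closest point on mesh surface for each query point.
// Returns unsigned distance, closest point, face index (1-based), and the
// sign from the angle-weighted pseudonormal at the closest feature.
// If VN (per-vertex normals) has rows, also returns the barycentric
// interpolation of vertex normals at the closest point.
// [[Rcpp::export]]
List cpp_surface_query(NumericMatrix P, NumericMatrix V, IntegerMatrix F,
                       NumericMatrix VN) {
  int nP = P.nrow(), nT = F.nrow(), nV = V.nrow();
  if (nT == 0 || nV == 0) stop("empty mesh");
  TriGrid g;
  buildGrid(V, F, g);

  // face normals (unit) and pseudonormals
  std::vector<Vec3> fn(nT);
  std::vector<Vec3> vertN(nV, v3(0, 0, 0));  // angle-weighted accumulation
  std::unordered_map<uint64_t, Vec3> edgeN;
  edgeN.reserve((size_t)nT * 2);
  for (int t = 0; t < nT; ++t) {
    int ia = F(t, 0) - 1, ib = F(t, 1) - 1, ic = F(t, 2) - 1;
    Vec3 a = v3(V(ia, 0), V(ia, 1), V(ia, 2));
    Vec3 b = v3(V(ib, 0), V(ib, 1), V(ib, 2));
    Vec3 c = v3(V(ic, 0), V(ic, 1), V(ic, 2));
    Vec3 n = normalize(cross(b - a, c - a));
    fn[t] = n;
    // angle weights
    Vec3 ea = normalize(b - a), ea2 = normalize(c - a);
    Vec3 eb = normalize(c - b), eb2 = normalize(a - b);
    Vec3 ec = normalize(a - c), ec2 = normalize(b - c);
    double wa = std::acos(std::max(-1.0, std::min(1.0, dot(ea, ea2))));
    double wb = std::acos(std::max(-1.0, std::min(1.0, dot(eb, eb2))));
    double wc = std::acos(std::max(-1.0, std::min(1.0, dot(ec, ec2))));
    vertN[ia] = vertN[ia] + wa * n;
    vertN[ib] = vertN[ib] + wb * n;
    vertN[ic] = vertN[ic] + wc * n;
    int vv[3] = {ia, ib, ic};
    for (int e = 0; e < 3; ++e) {
      uint64_t k = edgeKey(vv[e], vv[(e + 1) % 3]);
      auto it = edgeN.find(k);
      if (it == edgeN.end()) edgeN[k] = n; else it->second = it->second + n;
    }
  }

  bool haveVN = VN.nrow() == nV;
  NumericVector dist(nP), sgn(nP);
  NumericMatrix closest(nP, 3), nrm(nP, 3);
  IntegerVector face(nP);
  for (int q = 0; q < nP; ++q) {
    Vec3 p = v3(P(q, 0), P(q, 1), P(q, 2));
    double d2; int t, region; Vec3 cpt;
    queryGrid(g, V, F, p, d2, t, cpt, region);
    dist[q] = std::sqrt(d2);
    face[q] = t + 1;
    closest(q, 0) = cpt.x; closest(q, 1) = cpt.y; closest(q, 2) = cpt.z;
    int ia = F(t, 0) - 1, ib = F(t, 1) - 1, ic = F(t, 2) - 1;
    // pseudonormal for signing
    Vec3 pn;
    switch (region) {
      case 0: pn = fn[t]; break;
      case 1: pn = vertN[ia]; break;
      case 2: pn = vertN[ib]; break;
      case 3: pn = vertN[ic]; break;
      case 4: pn = edgeN[edgeKey(ia, ib)]; break;
      case 5: pn = edgeN[edgeKey(ib, ic)]; break;
      default: pn = edgeN[edgeKey(ic, ia)]; break;
    }
    double s = dot(p - cpt, pn);
    sgn[q] = (s >= 0) ? 1.0 : -1.0;
    // interpolated normal at closest point
    Vec3 nOut;
    if (haveVN) {
      Vec3 a = v3(V(ia, 0), V(ia, 1), V(ia, 2));
      Vec3 b = v3(V(ib, 0), V(ib, 1), V(ib, 2));
      Vec3 c = v3(V(ic, 0), V(ic, 1), V(ic, 2));
      // barycentric coordinates of cpt
      Vec3 v0 = b - a, v1 = c - a, v2 = cpt - a;
      double d00 = dot(v0, v0), d01 = dot(v0, v1), d11 = dot(v1, v1);
      double d20 = dot(v2, v0), d21 = dot(v2, v1);
      double den = d00 * d11 - d01 * d01;
      double bv = den > 0 ? (d11 * d20 - d01 * d21) / den : 0.0;
      double bw = den > 0 ? (d00 * d21 - d01 * d20) / den : 0.0;
      double bu = 1.0 - bv - bw;
      nOut = normalize(v3(
          bu * VN(ia, 0) + bv * VN(ib, 0) + bw * VN(ic, 0),
          bu * VN(ia, 1) + bv * VN(ib, 1) + bw * VN(ic, 1),
          bu * VN(ia, 2) + bv * VN(ib, 2) + bw * VN(ic, 2)));
    } else {
      nOut = fn[t];
    }
    nrm(q, 0) = nOut.x; nrm(q, 1) = nOut.y; nrm(q, 2) = nOut.z;
  }
  return List::create(_["distance"] = dist, _["sign"] = sgn,
                      _["closest"] = closest, _["normal"] = nrm,
                      _["face"] = face);
}

// Voxel-center inside test by z-ray parity. Returns logical vector in
// column-major array order for dims (nx, ny, nz).
// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh_grid(NumericMatrix V, IntegerMatrix F,
                                      NumericVector origin, double spacing,
                                      IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int nT = F.nrow();
  // bin triangles by x column range
  double ox = origin[0], oy = origin[1], oz = origin[2];
  // tiny irrational offset avoids rays through edges/vertices
  const double epsx = 1.0e-7 * spacing * 1.2345, epsy = 1.0e-7 * spacing * 2.3456;
  std::vector<std::vector<int>> colBins((size_t)nx * ny);
  for (int t = 0; t < nT; ++t) {
    double xlo = R_PosInf, xhi = R_NegInf, ylo = R_PosInf, yhi = R_NegInf;
    for (int c = 0; c < 3; ++c) {
      int vi = F(t, c) - 1;
      xlo = std::min(xlo, V(vi, 0)); xhi = std::max(xhi, V(vi, 0));
      ylo = std::min(ylo, V(vi, 1)); yhi = std::max(yhi, V(vi, 1));
    }
    int i0 = std::max(0, (int)std::ceil((xlo - ox) / spacing - 1e-9));
    int i1 = std::min(nx - 1, (int)std::floor((xhi - ox) / spacing + 1e-9));
    int j0 = std::max(0, (int)std::ceil((ylo - oy) / spacing - 1e-9));
    int j1 = std::min(ny - 1, (int)std::floor((yhi - oy) / spacing + 1e-9));
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i) colBins[(size_t)j * nx + i].push_back(t);
  }
  LogicalVector out((R_xlen_t)nx * ny * nz);
  std::vector<double> zs;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      double px = ox + i * spacing + epsx, py = oy + j * spacing + epsy;
      zs.clear();
      for (int t : colBins[(size_t)j * nx + i]) {
        int ia = F(t, 0) - 1, ib = F(t, 1) - 1, ic = F(t, 2) - 1;
        double ax = V(ia, 0) - px, ay = V(ia, 1) - py;
        double bx = V(ib, 0) - px, by = V(ib, 1) - py;
        double cx = V(ic, 0) - px, cy = V(ic, 1) - py;
        // 2D orientation tests
        double d1 = ax * by - ay * bx;
        double d2 = bx * cy - by * cx;
        double d3 = cx * ay - cy * ax;
        bool hasNeg = (d1 < 0) || (d2 < 0) || (d3 < 0);
        bool hasPos = (d1 > 0) || (d2 > 0) || (d3 > 0);
        if (hasNeg && hasPos) continue;  // outside projection
        double den = d1 + d2 + d3;
        if (den == 0) continue;  // degenerate projection
        double u = d2 / den, v = d3 / den, w = d1 / den;
        double z = u * V(ia, 2) + v * V(ib, 2) + w * V(ic, 2);
        zs.push_back(z);
      }
      if (zs.empty()) continue;
      std::sort(zs.begin(), zs.end());
      for (int k = 0; k < nz; ++k) {
        double pz = oz + k * spacing;
        // parity of crossings above pz
        size_t above = zs.end() - std::upper_bound(zs.begin(), zs.end(), pz);
        if (above % 2 == 1)
          out[(R_xlen_t)(k) * nx * ny + (R_xlen_t)j * nx + i] = true;
      }
    }
  }
  return out;
}
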