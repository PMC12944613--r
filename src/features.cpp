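// Coarse-registration support: deterministic voxel-grid downsampling, fast
// point feature histograms (FPFH, 3 x 11 bins), brute-force descriptor
// matching, and a seeded RANSAC over 3-point correspondences with edge-length
// pre-checks.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <algorithm>
#include <map>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

struct PGrid {
  double ox, oy, oz, cell;
  int nx, ny, nz;
  std::vector<std::vector<int>> bins;
  int clampi(int v, int hi) const { return v < 0 ? 0 : (v >= hi ? hi - 1 : v); }
  size_t idx(int i, int j, int k) const { return ((size_t)k * ny + j) * nx + i; }
};

void buildPGrid(const NumericMatrix& P, double cell, PGrid& g) {
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < P.nrow(); ++i)
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], P(i, d));
      hi[d] = std::max(hi[d], P(i, d));
    }
  g.cell = cell;
  g.ox = lo[0] - cell; g.oy = lo[1] - cell; g.oz = lo[2] - cell;
  g.nx = std::max(1, (int)((hi[0] - g.ox) / cell) + 2);
  g.ny = std::max(1, (int)((hi[1] - g.oy) / cell) + 2);
  g.nz = std::max(1, (int)((hi[2] - g.oz) / cell) + 2);
  g.bins.assign((size_t)g.nx * g.ny * g.nz, {});
  for (int i = 0; i < P.nrow(); ++i) {
    int ci = g.clampi((int)((P(i, 0) - g.ox) / cell), g.nx);
    int cj = g.clampi((int)((P(i, 1) - g.oy) / cell), g.ny);
    int ck = g.clampi((int)((P(i, 2) - g.oz) / cell), g.nz);
    g.bins[g.idx(ci, cj, ck)].push_back(i);
  }
}

void radiusNeighbors(const PGrid& g, const NumericMatrix& P, int q, double radius,
                     std::vector<int>& out, std::vector<double>& dists) {
  out.clear(); dists.clear();
  double r2 = radius * radius;
  int span = (int)std::ceil(radius / g.cell);
  int ci = g.clampi((int)((P(q, 0) - g.ox) / g.cell), g.nx);
  int cj = g.clampi((int)((P(q, 1) - g.oy) / g.cell), g.ny);
  int ck = g.clampi((int)((P(q, 2) - g.oz) / g.cell), g.nz);
  for (int k = std::max(0, ck - span); k <= std::min(g.nz - 1, ck + span); ++k)
    for (int j = std::max(0, cj - span); j <= std::min(g.ny - 1, cj + span); ++j)
      for (int i = std::max(0, ci - span); i <= std::min(g.nx - 1, ci + span); ++i)
        for (int p : g.bins[g.idx(i, j, k)]) {
          if (p == q) continue;
          double dx = P(p, 0) - P(q, 0), dy = P(p, 1) - P(q, 1), dz = P(p, 2) - P(q, 2);
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 <= r2) { out.push_back(p); dists.push_back(std::sqrt(d2)); }
        }
}

// xorshift64* PRNG: all RANSAC randomness flows from the caller's seed
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed ? seed : 0x9e3779b97f4a7c15ull) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 2685821657736338717ull;
  }
  int uniformInt(int n) { return (int)(next() % (uint64_t)n); }
};

}  // namespace

// Deterministic voxel-grid downsampling: centroid of points per occupied
// cell, normals averaged and renormalized; cells emitted in sorted key order.
// [[Rcpp::export]]
List cpp_voxel_downsample(NumericMatrix P, NumericMatrix N, double voxel) {
  int n = P.nrow();
  bool haveN = N.nrow() == n;
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) lo[d] = std::min(lo[d], P(i, d));
  std::map<std::tuple<long long, long long, long long>, std::vector<int>> cells;
  for (int i = 0; i < n; ++i) {
    long long a = (long long)std::floor((P(i, 0) - lo[0]) / voxel);
    long long b = (long long)std::floor((P(i, 1) - lo[1]) / voxel);
    long long c = (long long)std::floor((P(i, 2) - lo[2]) / voxel);
    cells[{a, b, c}].push_back(i);
  }
  int m = (int)cells.size();
  NumericMatrix Q(m, 3), QN(haveN ? m : 0, 3);
  int r = 0;
  for (auto& kv : cells) {
    double cx = 0, cy = 0, cz = 0, nxx = 0, nyy = 0, nzz = 0;
    for (int i : kv.second) {
      cx += P(i, 0); cy += P(i, 1); cz += P(i, 2);
      if (haveN) { nxx += N(i, 0); nyy += N(i, 1); nzz += N(i, 2); }
    }
    double k = (double)kv.second.size();
    Q(r, 0) = cx / k; Q(r, 1) = cy / k; Q(r, 2) = cz / k;
    if (haveN) {
      double nn = std::sqrt(nxx * nxx + nyy * nyy + nzz * nzz);
      if (nn == 0) nn = 1;
      QN(r, 0) = nxx / nn; QN(r, 1) = nyy / nn; QN(r, 2) = nzz / nn;
    }
    ++r;
  }
  return List::create(_["points"] = Q, _["normals"] = QN);
}

// FPFH descriptors (33 bins) on an oriented point cloud.
// [[Rcpp::export]]
NumericMatrix cpp_fpfh(NumericMatrix P, NumericMatrix N, double radius) {
  int n = P.nrow();
  PGrid g;
  buildPGrid(P, radius, g);
  NumericMatrix spfh(n, 33);
  std::vector<std::vector<int>> nbrs(n);
  std::vector<std::vector<double>> nbrd(n);
  std::vector<int> nb;
  std::vector<double> nd;
  for (int q = 0; q < n; ++q) {
    radiusNeighbors(g, P, q, radius, nb, nd);
    nbrs[q] = nb; nbrd[q] = nd;
    if (nb.empty()) continue;
    for (size_t t = 0; t < nb.size(); ++t) {
      int p = nb[t];
      double dx = P(p, 0) - P(q, 0), dy = P(p, 1) - P(q, 1), dz = P(p, 2) - P(q, 2);
      double dn = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (dn == 0) continue;
      dx /= dn; dy /= dn; dz /= dn;
      // Darboux frame at source q
      double ux = N(q, 0), uy = N(q, 1), uz = N(q, 2);
      double vx = uy * dz - uz * dy, vy = uz * dx - ux * dz, vz = ux * dy - uy * dx;
      double vn = std::sqrt(vx * vx + vy * vy + vz * vz);
      if (vn == 0) continue;
      vx /= vn; vy /= vn; vz /= vn;
      double wx = uy * vz - uz * vy, wy = uz * vx - ux * vz, wz = ux * vy - uy * vx;
      double alpha = vx * N(p, 0) + vy * N(p, 1) + vz * N(p, 2);       // in [-1,1]
      double phi = ux * dx + uy * dy + uz * dz;                        // in [-1,1]
      double theta = std::atan2(wx * N(p, 0) + wy * N(p, 1) + wz * N(p, 2),
                                ux * N(p, 0) + uy * N(p, 1) + uz * N(p, 2));
      int b0 = std::min(10, std::max(0, (int)(11.0 * (alpha + 1.0) / 2.0)));
      int b1 = std::min(10, std::max(0, (int)(11.0 * (phi + 1.0) / 2.0)));
      int b2 = std::min(10, std::max(0, (int)(11.0 * (theta + M_PI) / (2.0 * M_PI))));
      spfh(q, b0) += 1; spfh(q, 11 + b1) += 1; spfh(q, 22 + b2) += 1;
    }
    // normalize each feature block to 100
    for (int blk = 0; blk < 3; ++blk) {
      double s = 0;
      for (int b = 0; b < 11; ++b) s += spfh(q, 11 * blk + b);
      if (s > 0)
        for (int b = 0; b < 11; ++b) spfh(q, 11 * blk + b) *= 100.0 / s;
    }
  }
  NumericMatrix fpfh(n, 33);
  for (int q = 0; q < n; ++q) {
    for (int b = 0; b < 33; ++b) fpfh(q, b) = spfh(q, b);
    if (nbrs[q].empty()) continue;
    double k = (double)nbrs[q].size();
    for (size_t t = 0; t < nbrs[q].size(); ++t) {
      int p = nbrs[q][t];
      double w = std::max(nbrd[q][t], 1e-9);
      for (int b = 0; b < 33; ++b) fpfh(q, b) += spfh(p, b) / (k * w);
    }
  }
  return fpfh;
}

// For each row of A, index (1-based) of the nearest row of B (L2).
// [[Rcpp::export]]
IntegerVector cpp_nn_rows(NumericMatrix A, NumericMatrix B) {
  int n = A.nrow(), m = B.nrow(), d = A.ncol();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bj = 0;
    for (int j = 0; j < m; ++j) {
      double s = 0;
      for (int c = 0; c < d; ++c) {
        double t = A(i, c) - B(j, c);
        s += t * t;
        if (s >= best) break;
      }
      if (s < best) { best = s; bj = j; }
    }
    out[i] = bj + 1;
  }
  return out;
}

namespace {

// rigid transform from 3 exact correspondences via orthonormal frames
bool rigidFrom3(const double S[3][3], const double D[3][3], double R[3][3], double t[3]) {
  auto frame = [](const double Pt[3][3], double Fm[3][3]) -> bool {
    double e1[3] = {Pt[1][0] - Pt[0][0], Pt[1][1] - Pt[0][1], Pt[1][2] - Pt[0][2]};
    double e2[3] = {Pt[2][0] - Pt[0][0], Pt[2][1] - Pt[0][1], Pt[2][2] - Pt[0][2]};
    double n1 = std::sqrt(e1[0] * e1[0] + e1[1] * e1[1] + e1[2] * e1[2]);
    if (n1 < 1e-12) return false;
    for (int d = 0; d < 3; ++d) e1[d] /= n1;
    double c[3] = {e1[1] * e2[2] - e1[2] * e2[1], e1[2] * e2[0] - e1[0] * e2[2],
                   e1[0] * e2[1] - e1[1] * e2[0]};
    double nc = std::sqrt(c[0] * c[0] + c[1] * c[1] + c[2] * c[2]);
    if (nc < 1e-12) return false;
    for (int d = 0; d < 3; ++d) c[d] /= nc;
    double b[3] = {c[1] * e1[2] - c[2] * e1[1], c[2] * e1[0] - c[0] * e1[2],
                   c[0] * e1[1] - c[1] * e1[0]};
    for (int d = 0; d < 3; ++d) {
      Fm[d][0] = e1[d]; Fm[d][1] = b[d]; Fm[d][2] = c[d];
    }
    return true;
  };
  double Fs[3][3], Fd[3][3];
  if (!frame(S, Fs) || !frame(D, Fd)) return false;
  // R = Fd * Fs^T
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      R[i][j] = 0;
      for (int k = 0; k < 3; ++k) R[i][j] += Fd[i][k] * Fs[j][k];
    }
  double cS[3] = {(S[0][0] + S[1][0] + S[2][0]) / 3, (S[0][1] + S[1][1] + S[2][1]) / 3,
                  (S[0][2] + S[1][2] + S[2][2]) / 3};
  double cD[3] = {(D[0][0] + D[1][0] + D[2][0]) / 3, (D[0][1] + D[1][1] + D[2][1]) / 3,
                  (D[0][2] + D[1][2] + D[2][2]) / 3};
  for (int d = 0; d < 3; ++d)
    t[d] = cD[d] - (R[d][0] * cS[0] + R[d][1] * cS[1] + R[d][2] * cS[2]);
  return true;
}

}  // namespace

// Seeded RANSAC over fixed descriptor correspondences corr (1-based rows into
// src/dst). Hypotheses from 3 sampled correspondences pass edge-length
// similarity (|1 - lsrc/ldst| <= edgeTol) before inlier counting at
// distThresh against the corresponding dst points. Early exit at 0.999
// confidence. Returns best R, t, inlier indices.
// [[Rcpp::export]]
List cpp_ransac_align(NumericMatrix src, NumericMatrix dst, IntegerMatrix corr,
                      int maxIter, double distThresh, double edgeTol,
                      double seed) {
  int nc = corr.nrow();
  if (nc < 3) stop("need at least 3 correspondences");
  Rng rng((uint64_t)seed);
  double bestR[3][3], bestT[3];
  int bestInl = -1;
  double bestErr = R_PosInf;
  int it = 0, needed = maxIter;
  for (it = 0; it < maxIter && it < needed; ++it) {
    int i1 = rng.uniformInt(nc), i2 = rng.uniformInt(nc), i3 = rng.uniformInt(nc);
    if (i1 == i2 || i1 == i3 || i2 == i3) continue;
    int sIdx[3] = {corr(i1, 0) - 1, corr(i2, 0) - 1, corr(i3, 0) - 1};
    int dIdx[3] = {corr(i1, 1) - 1, corr(i2, 1) - 1, corr(i3, 1) - 1};
    double S[3][3], D[3][3];
    for (int a = 0; a < 3; ++a)
      for (int d = 0; d < 3; ++d) {
        S[a][d] = src(sIdx[a], d);
        D[a][d] = dst(dIdx[a], d);
      }
    // edge-length check
    bool ok = true;
    for (int a = 0; a < 3 && ok; ++a) {
      int b = (a + 1) % 3;
      double ls = 0, ld = 0;
      for (int d = 0; d < 3; ++d) {
        double es = S[a][d] - S[b][d], ed = D[a][d] - D[b][d];
        ls += es * es; ld += ed * ed;
      }
      ls = std::sqrt(ls); ld = std::sqrt(ld);
      if (ld < 1e-9 || std::fabs(1.0 - ls / ld) > edgeTol) ok = false;
    }
    if (!ok) continue;
    double R[3][3], t[3];
    if (!rigidFrom3(S, D, R, t)) continue;
    // distance check on the 3 sampled correspondences first
    ok = true;
    for (int a = 0; a < 3 && ok; ++a) {
      double e2 = 0;
      for (int d = 0; d < 3; ++d) {
        double m = R[d][0] * S[a][0] + R[d][1] * S[a][1] + R[d][2] * S[a][2] + t[d] - D[a][d];
        e2 += m * m;
      }
      if (e2 > distThresh * distThresh) ok = false;
    }
    if (!ok) continue;
    // full inlier count over all correspondences
    int inl = 0;
    double err = 0;
    for (int c = 0; c < nc; ++c) {
      int si = corr(c, 0) - 1, di = corr(c, 1) - 1;
      double e2 = 0;
      for (int d = 0; d < 3; ++d) {
        double m = R[d][0] * src(si, 0) + R[d][1] * src(si, 1) + R[d][2] * src(si, 2) +
                   t[d] - dst(di, d);
        e2 += m * m;
      }
      if (e2 <= distThresh * distThresh) { ++inl; err += e2; }
    }
    if (inl > bestInl || (inl == bestInl && err < bestErr)) {
      bestInl = inl; bestErr = err;
      for (int a = 0; a < 3; ++a) {
        bestT[a] = t[a];
        for (int b = 0; b < 3; ++b) bestR[a][b] = R[a][b];
      }
      // 0.999 confidence early exit
      double w = (double)inl / nc;
      if (w > 0) {
        double denom = std::log(1.0 - std::min(0.999999, w * w * w));
        if (denom < 0) {
          int est = (int)std::ceil(std::log(1.0 - 0.999) / denom);
          needed = std::min(maxIter, std::max(it + 1, est));
        }
      }
    }
  }
  if (bestInl < 3) stop("RANSAC found no hypothesis with at least 3 inliers");
  NumericMatrix R(3, 3);
  NumericVector t(3);
  for (int a = 0; a < 3; ++a) {
    t[a] = bestT[a];
    for (int b = 0; b < 3; ++b) R(a, b) = bestR[a][b];
  }
  // inlier correspondence rows under the best hypothesis
  std::vector<int> inliers;
  for (int c = 0; c < nc; ++c) {
    int si = corr(c, 0) - 1, di = corr(c, 1) - 1;
    double e2 = 0;
    for (int d = 0; d < 3; ++d) {
      double m = bestR[d][0] * src(si, 0) + bestR[d][1] * src(si, 1) +
                 bestR[d][2] * src(si, 2) + bestT[d] - dst(di, d);
      e2 += m * m;
    }
    if (e2 <= distThresh * distThresh) inliers.push_back(c + 1);
  }
  return List::create(_["rotation"] = R, _["translation"] = t,
                      _["inliers"] = wrap(inliers), _["iterations"] = it);
}
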