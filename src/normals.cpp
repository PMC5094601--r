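#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

namespace {

// Jacobi eigen decomposition of a symmetric 3x3; returns the eigenvector of
// the smallest eigenvalue (the local surface normal of a planar patch).
void smallest_eigvec(double a[3][3], double v[3]) {
  double q[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
  for (int sweep = 0; sweep < 24; ++sweep) {
    double off = std::fabs(a[0][1]) + std::fabs(a[0][2]) + std::fabs(a[1][2]);
    if (off < 1e-15) break;
    for (int p = 0; p < 2; ++p) {
      for (int qq = p + 1; qq < 3; ++qq) {
        if (std::fabs(a[p][qq]) < 1e-18) continue;
        const double theta = (a[qq][qq] - a[p][p]) / (2.0 * a[p][qq]);
        const double t = (theta >= 0 ? 1.0 : -1.0) /
                         (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        const double c = 1.0 / std::sqrt(t * t + 1.0), s = t * c;
        for (int k = 0; k < 3; ++k) {
          const double akp = a[k][p], akq = a[k][qq];
          a[k][p] = c * akp - s * akq;
          a[k][qq] = s * akp + c * akq;
        }
        for (int k = 0; k < 3; ++k) {
          const double apk = a[p][k], aqk = a[qq][k];
          a[p][k] = c * apk - s * aqk;
          a[qq][k] = s * apk + c * aqk;
        }
        for (int k = 0; k < 3; ++k) {
          const double qkp = q[k][p], qkq = q[k][qq];
          q[k][p] = c * qkp - s * qkq;
          q[k][qq] = s * qkp + c * qkq;
        }
      }
    }
  }
  int imin = 0;
  if (a[1][1] < a[imin][imin]) imin = 1;
  if (a[2][2] < a[imin][imin]) imin = 2;
  for (int k = 0; k < 3; ++k) v[k] = q[k][imin];
}

inline int64_t cell_key(int ix, int iy, int iz) {
  return (int64_t)ix * 73856093LL ^ (int64_t)iy * 19349663LL ^
         (int64_t)iz * 83492791LL;
}

}  // namespace

// PCA normals from the k nearest neighbours (self included), found with a
// uniform hash grid. Normals are sign-oriented toward the per-point camera
// position when it is finite; undefined normals (cloud smaller than k, or a
// degenerate neighbourhood) come back as NaN.
// [[Rcpp::export]]
NumericMatrix cpp_knn_normals(NumericMatrix P, int k, NumericMatrix campos) {
  const int n = P.nrow();
  NumericMatrix N(n, 3);
  std::fill(N.begin(), N.end(), NA_REAL);
  if (n < k || k < 3) return N;

  // cell size targeting ~k points per cell; depth-camera clouds are
  // surface-like, so the density estimate uses the two largest extents
  double lo[3], hi[3], ext[3];
  for (int c = 0; c < 3; ++c) { lo[c] = R_PosInf; hi[c] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      lo[c] = std::min(lo[c], P(i, c));
      hi[c] = std::max(hi[c], P(i, c));
    }
  for (int c = 0; c < 3; ++c) ext[c] = std::max(hi[c] - lo[c], 1e-6);
  std::sort(ext, ext + 3);
  double cell = std::sqrt(ext[1] * ext[2] * k / std::max(1, n));
  cell = std::max(cell, 1e-6);

  std::unordered_map<int64_t, std::vector<int> > grid;
  grid.reserve(2 * n);
  std::vector<int> gx(n), gy(n), gz(n);
  for (int i = 0; i < n; ++i) {
    gx[i] = (int)std::floor((P(i, 0) - lo[0]) / cell);
    gy[i] = (int)std::floor((P(i, 1) - lo[1]) / cell);
    gz[i] = (int)std::floor((P(i, 2) - lo[2]) / cell);
    grid[cell_key(gx[i], gy[i], gz[i])].push_back(i);
  }

  std::vector<std::pair<double, int> > cand;
  for (int i = 0; i < n; ++i) {
    cand.clear();
    // grow shells outward until k candidates are found, then one shell
    // further so points just outside the first successful shell are seen
    int found_at = -1;
    for (int ring = 0; ring <= 64; ++ring) {
      for (int ix = gx[i] - ring; ix <= gx[i] + ring; ++ix)
        for (int iy = gy[i] - ring; iy <= gy[i] + ring; ++iy)
          for (int iz = gz[i] - ring; iz <= gz[i] + ring; ++iz) {
            // only the new outer shell of this ring
            if (std::max(std::abs(ix - gx[i]),
                         std::max(std::abs(iy - gy[i]),
                                  std::abs(iz - gz[i]))) != ring)
              continue;
            auto it = grid.find(cell_key(ix, iy, iz));
            if (it == grid.end()) continue;
            for (int j : it->second) {
              if (ix != gx[j] || iy != gy[j] || iz != gz[j]) continue;
              const double dx = P(j, 0) - P(i, 0), dy = P(j, 1) - P(i, 1),
                           dz = P(j, 2) - P(i, 2);
              cand.push_back(std::make_pair(dx * dx + dy * dy + dz * dz, j));
            }
          }
      if (found_at >= 0 && ring > found_at) break;
      if ((int)cand.size() >= k && found_at < 0) found_at = ring;
    }
    if ((int)cand.size() < k) continue;
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());

    double mx = 0, my = 0, mz = 0;
    for (int t = 0; t < k; ++t) {
      const int j = cand[t].second;
      mx += P(j, 0); my += P(j, 1); mz += P(j, 2);
    }
    mx /= k; my /= k; mz /= k;
    double C[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    for (int t = 0; t < k; ++t) {
      const int j = cand[t].second;
      const double dx = P(j, 0) - mx, dy = P(j, 1) - my, dz = P(j, 2) - mz;
      C[0][0] += dx * dx; C[0][1] += dx * dy; C[0][2] += dx * dz;
      C[1][1] += dy * dy; C[1][2] += dy * dz; C[2][2] += dz * dz;
    }
    C[1][0] = C[0][1]; C[2][0] = C[0][2]; C[2][1] = C[1][2];
    double tr = C[0][0] + C[1][1] + C[2][2];
    if (tr < 1e-18) continue;
    double v[3];
    smallest_eigvec(C, v);
    const double nv = std::sqrt(v[0] * v[0] + v[1] * v[1] + v[2] * v[2]);
    if (nv < 1e-12) continue;
    v[0] /= nv; v[1] /= nv; v[2] /= nv;
    if (campos.nrow() == n && R_finite(campos(i, 0))) {
      const double tox = campos(i, 0) - P(i, 0), toy = campos(i, 1) - P(i, 1),
                   toz = campos(i, 2) - P(i, 2);
      if (v[0] * tox + v[1] * toy + v[2] * toz < 0) {
        v[0] = -v[0]; v[1] = -v[1]; v[2] = -v[2];
      }
    }
    N(i, 0) = v[0]; N(i, 1) = v[1]; N(i, 2) = v[2];
  }
  return N;
}
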