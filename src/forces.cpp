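#include <Rcpp.h>
using namespace Rcpp;

// Attraction force field. For every cloud point j the set of spheres whose
// small exclusion ball B_k contains it is found; a point claimed by two or
// more spheres attracts nobody, a point claimed by exactly one sphere may
// only attract that sphere, and an unclaimed point attracts every sphere
// whose large region A_i contains it. Balls are closed (<=).
// [[Rcpp::export]]
List cpp_attraction(NumericMatrix P, NumericMatrix S, NumericVector radius,
                    NumericVector mass, double alpha,
                    double regionA_factor, double regionB_factor) {
  const int n = P.nrow(), m = S.nrow();
  NumericMatrix F(m, 3);
  std::vector< std::vector<int> > act(m);
  std::vector<double> d2(m);
  for (int j = 0; j < n; ++j) {
    const double px = P(j, 0), py = P(j, 1), pz = P(j, 2);
    int bcount = 0, bid = -1;
    for (int k = 0; k < m; ++k) {
      const double dx = px - S(k, 0), dy = py - S(k, 1), dz = pz - S(k, 2);
      d2[k] = dx * dx + dy * dy + dz * dz;
      const double rb = regionB_factor * radius[k];
      if (d2[k] <= rb * rb) { ++bcount; bid = k; }
    }
    if (bcount >= 2) continue;
    for (int i = 0; i < m; ++i) {
      if (bcount == 1 && bid != i) continue;
      const double ra = regionA_factor * radius[i];
      if (d2[i] <= ra * ra) {
        F(i, 0) += px - S(i, 0);
        F(i, 1) += py - S(i, 1);
        F(i, 2) += pz - S(i, 2);
        act[i].push_back(j + 1);
      }
    }
  }
  for (int i = 0; i < m; ++i) {
    const double c = alpha * mass[i];
    F(i, 0) *= c; F(i, 1) *= c; F(i, 2) *= c;
  }
  List actR(m);
  for (int i = 0; i < m; ++i)
    actR[i] = IntegerVector(act[i].begin(), act[i].end());
  return List::create(_["force"] = F, _["active"] = actR);
}

// Repulsion force field. A point j acts on sphere i when it lies inside the
// gating ball C_i and its (camera-oriented) normal sees the sphere center on
// the interior side, N_j . (P_j - S_i) > 0. Each active point contributes a
// unit vector scaled by beta * m_i; `sign` = -1 pushes the sphere away from
// the point (the confining behavior), +1 reproduces the attractive sign.
// Points with undefined normals among gated points are skipped and counted.
// [[Rcpp::export]]
List cpp_repulsion(NumericMatrix P, NumericMatrix N, NumericMatrix S,
                   NumericVector radius, NumericVector mass, double beta,
                   double regionC_factor, double sign) {
  const int n = P.nrow(), m = S.nrow();
  NumericMatrix F(m, 3);
  std::vector< std::vector<int> > act(m);
  int n_skipped = 0;
  for (int j = 0; j < n; ++j) {
    const double px = P(j, 0), py = P(j, 1), pz = P(j, 2);
    const double nx = N(j, 0), ny = N(j, 1), nz = N(j, 2);
    const bool nok = R_finite(nx) && R_finite(ny) && R_finite(nz);
    bool counted = false;
    for (int i = 0; i < m; ++i) {
      const double dx = px - S(i, 0), dy = py - S(i, 1), dz = pz - S(i, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double rc = regionC_factor * radius[i];
      if (d2 > rc * rc) continue;
      if (!nok) { if (!counted) { ++n_skipped; counted = true; } continue; }
      if (nx * dx + ny * dy + nz * dz <= 0.0) continue;
      const double d = std::sqrt(d2);
      if (d < 1e-12) continue;
      F(i, 0) += sign * dx / d;
      F(i, 1) += sign * dy / d;
      F(i, 2) += sign * dz / d;
      act[i].push_back(j + 1);
    }
  }
  for (int i = 0; i < m; ++i) {
    const double c = beta * mass[i];
    F(i, 0) *= c; F(i, 1) *= c; F(i, 2) *= c;
  }
  List actR(m);
  for (int i = 0; i < m; ++i)
    actR[i] = IntegerVector(act[i].begin(), act[i].end());
  return List::create(_["force"] = F, _["active"] = actR,
                      _["n_skipped"] = n_skipped);
}
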