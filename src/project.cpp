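#include <Rcpp.h>
using namespace Rcpp;

namespace {

inline double norm3(double x, double y, double z) {
  return std::sqrt(x * x + y * y + z * z);
}

// deterministic unit vector perpendicular to u
void any_perp(const double u[3], double out[3]) {
  int imin = 0;
  if (std::fabs(u[1]) < std::fabs(u[imin])) imin = 1;
  if (std::fabs(u[2]) < std::fabs(u[imin])) imin = 2;
  double e[3] = {0, 0, 0};
  e[imin] = 1.0;
  out[0] = u[1] * e[2] - u[2] * e[1];
  out[1] = u[2] * e[0] - u[0] * e[2];
  out[2] = u[0] * e[1] - u[1] * e[0];
  const double n = norm3(out[0], out[1], out[2]);
  out[0] /= n; out[1] /= n; out[2] /= n;
}

}  // namespace

// Positional constraint projection for the articulated sphere chain.
// `parent`, `child`, `grand` are 0-based sphere indices per joint in
// root-to-leaf topological order (`grand` = -1 when the parent bone has no
// parent bone, leaving that joint's bend angle unconstrained). Bend limits
// are radians measured between the parent bone vector and the child bone
// vector (0 = the chain continues straight).
//
// Stage 1: nsweeps Gauss-Seidel sweeps of bilateral, inverse-mass-weighted
// distance corrections (spreads large violations over the whole chain).
// Stage 2: one ordered root-to-leaf pass per joint that (a) rescales the
// child onto the exact rest length and (b) rotates the child about the
// parent to clamp the bend angle into its limits; the rotation preserves the
// length and parents are final before their children, so on exit every bone
// length is exact to machine precision and every constrained angle in range.
// [[Rcpp::export]]
NumericMatrix cpp_project_constraints(NumericMatrix C0, IntegerVector parent,
                                      IntegerVector child, IntegerVector grand,
                                      NumericVector restlen,
                                      NumericVector bendmin,
                                      NumericVector bendmax,
                                      NumericVector invmass, int nsweeps) {
  NumericMatrix C = clone(C0);
  const int nj = parent.size();

  for (int s = 0; s < nsweeps; ++s) {
    for (int j = 0; j < nj; ++j) {
      const int p = parent[j], c = child[j];
      double dx = C(c, 0) - C(p, 0), dy = C(c, 1) - C(p, 1),
             dz = C(c, 2) - C(p, 2);
      double d = norm3(dx, dy, dz);
      if (d < 1e-12) { dx = 1.0; dy = 0.0; dz = 0.0; d = 1.0; }
      const double err = d - restlen[j];
      const double wsum = invmass[p] + invmass[c];
      if (wsum <= 0.0) continue;
      const double wp = invmass[p] / wsum, wc = invmass[c] / wsum;
      const double ux = dx / d, uy = dy / d, uz = dz / d;
      C(p, 0) += wp * err * ux; C(p, 1) += wp * err * uy;
      C(p, 2) += wp * err * uz;
      C(c, 0) -= wc * err * ux; C(c, 1) -= wc * err * uy;
      C(c, 2) -= wc * err * uz;
    }
  }

  for (int j = 0; j < nj; ++j) {
    const int p = parent[j], c = child[j], g = grand[j];
    double vx = C(c, 0) - C(p, 0), vy = C(c, 1) - C(p, 1),
           vz = C(c, 2) - C(p, 2);
    double nv = norm3(vx, vy, vz);
    if (nv < 1e-12) { vx = 1.0; vy = 0.0; vz = 0.0; nv = 1.0; }
    vx /= nv; vy /= nv; vz /= nv;

    if (g >= 0) {
      double u[3] = {C(p, 0) - C(g, 0), C(p, 1) - C(g, 1), C(p, 2) - C(g, 2)};
      const double nu = norm3(u[0], u[1], u[2]);
      if (nu > 1e-12) {
        u[0] /= nu; u[1] /= nu; u[2] /= nu;
        double cosb = u[0] * vx + u[1] * vy + u[2] * vz;
        cosb = std::max(-1.0, std::min(1.0, cosb));
        const double bend = std::acos(cosb);
        double target = bend;
        if (bend < bendmin[j]) target = bendmin[j];
        if (bend > bendmax[j]) target = bendmax[j];
        if (target != bend) {
          // rotate v in the plane span(u, v) about w = u x v; positive
          // rotation about w increases the angle between u and v
          double w[3] = {u[1] * vz - u[2] * vy, u[2] * vx - u[0] * vz,
                         u[0] * vy - u[1] * vx};
          const double nw = norm3(w[0], w[1], w[2]);
          if (nw > 1e-9) {
            w[0] /= nw; w[1] /= nw; w[2] /= nw;
          } else {
            any_perp(u, w);
          }
          const double phi = target - bend;
          const double cph = std::cos(phi), sph = std::sin(phi);
          const double wxv[3] = {w[1] * vz - w[2] * vy, w[2] * vx - w[0] * vz,
                                 w[0] * vy - w[1] * vx};
          const double nvx = vx * cph + wxv[0] * sph;
          const double nvy = vy * cph + wxv[1] * sph;
          const double nvz = vz * cph + wxv[2] * sph;
          vx = nvx; vy = nvy; vz = nvz;
        }
      }
    }

    C(c, 0) = C(p, 0) + restlen[j] * vx;
    C(c, 1) = C(p, 1) + restlen[j] * vy;
    C(c, 2) = C(p, 2) + restlen[j] * vz;
  }
  return C;
}
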