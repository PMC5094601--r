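#include <Rcpp.h>
using namespace Rcpp;

// Z-buffer ray cast of a union of spheres and capsules. Rays are
// origin + t * dir; dir need not be unit length, so with camera-frame
// directions ((u-cx)/fx, (v-cy)/fy, 1) mapped to world, the returned t is
// directly the camera-axis depth. Returns the nearest hit parameter per ray
// (Inf for a miss) and the 1-based primitive index (spheres first, then
// capsules; 0 for a miss).
// [[Rcpp::export]]
List cpp_raycast(NumericVector origin, NumericMatrix D,
                 NumericMatrix sph_c, NumericVector sph_r,
                 NumericMatrix cap_a, NumericMatrix cap_b,
                 NumericVector cap_r) {
  const int n = D.nrow(), ns = sph_c.nrow(), nc = cap_a.nrow();
  NumericVector tout(n, R_PosInf);
  IntegerVector prim(n, 0);
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double tmin = 1e-6;

  for (int i = 0; i < n; ++i) {
    const double dx = D(i, 0), dy = D(i, 1), dz = D(i, 2);
    const double dd = dx * dx + dy * dy + dz * dz;
    double tbest = R_PosInf;
    int pbest = 0;

    for (int s = 0; s < ns; ++s) {
      const double mx = ox - sph_c(s, 0), my = oy - sph_c(s, 1),
                   mz = oz - sph_c(s, 2);
      const double b = mx * dx + my * dy + mz * dz;
      const double c = mx * mx + my * my + mz * mz - sph_r[s] * sph_r[s];
      const double disc = b * b - dd * c;
      if (disc < 0.0) continue;
      const double t = (-b - std::sqrt(disc)) / dd;
      if (t > tmin && t < tbest) { tbest = t; pbest = s + 1; }
    }

    for (int s = 0; s < nc; ++s) {
      // infinite cylinder about segment a-b, hits kept only when the foot of
      // the hit point falls within the segment (end caps are covered by the
      // joint spheres of the union)
      const double axx = cap_b(s, 0) - cap_a(s, 0),
                   axy = cap_b(s, 1) - cap_a(s, 1),
                   axz = cap_b(s, 2) - cap_a(s, 2);
      const double L2 = axx * axx + axy * axy + axz * axz;
      if (L2 < 1e-16) continue;
      const double mx = ox - cap_a(s, 0), my = oy - cap_a(s, 1),
                   mz = oz - cap_a(s, 2);
      const double da = dx * axx + dy * axy + dz * axz;
      const double ma = mx * axx + my * axy + mz * axz;
      const double A = dd - da * da / L2;
      const double B = (mx * dx + my * dy + mz * dz) - da * ma / L2;
      const double C = (mx * mx + my * my + mz * mz) - ma * ma / L2 -
                       cap_r[s] * cap_r[s];
      if (std::fabs(A) < 1e-16) continue;
      const double disc = B * B - A * C;
      if (disc < 0.0) continue;
      const double t = (-B - std::sqrt(disc)) / A;
      if (t <= tmin || t >= tbest) continue;
      const double u = (ma + t * da) / L2;
      if (u < 0.0 || u > 1.0) continue;
      tbest = t; pbest = ns + s + 1;
    }

    tout[i] = tbest;
    prim[i] = pbest;
  }
  return List::create(_["t"] = tout, _["prim"] = prim);
}
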