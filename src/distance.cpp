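#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Squared distance from point p to triangle (a, b, c), Eberly's
// region-based closed form on the parameter domain {s >= 0, t >= 0,
// s + t <= 1} of T(s, t) = a + s*(b - a) + t*(c - a).
static double point_tri_dist2(const double *p, const double *a,
                              const double *b, const double *c) {
  double E0[3], E1[3], D[3];
  for (int i = 0; i < 3; ++i) {
    E0[i] = b[i] - a[i];
    E1[i] = c[i] - a[i];
    D[i] = a[i] - p[i];
  }
  double A = E0[0]*E0[0] + E0[1]*E0[1] + E0[2]*E0[2];
  double B = E0[0]*E1[0] + E0[1]*E1[1] + E0[2]*E1[2];
  double C = E1[0]*E1[0] + E1[1]*E1[1] + E1[2]*E1[2];
  double Dd = E0[0]*D[0] + E0[1]*D[1] + E0[2]*D[2];
  double E = E1[0]*D[0] + E1[1]*D[1] + E1[2]*D[2];
  double F = D[0]*D[0] + D[1]*D[1] + D[2]*D[2];

  double det = A*C - B*B;
  double s = B*E - C*Dd;
  double t = B*Dd - A*E;

  if (s + t <= det) {
    if (s < 0.0) {
      if (t < 0.0) {               // region 4
        if (Dd < 0.0) {
          t = 0.0;
          s = (-Dd >= A ? 1.0 : -Dd / A);
        } else {
          s = 0.0;
          t = (E >= 0.0 ? 0.0 : (-E >= C ? 1.0 : -E / C));
        }
      } else {                     // region 3
        s = 0.0;
        t = (E >= 0.0 ? 0.0 : (-E >= C ? 1.0 : -E / C));
      }
    } else if (t < 0.0) {          // region 5
      t = 0.0;
      s = (Dd >= 0.0 ? 0.0 : (-Dd >= A ? 1.0 : -Dd / A));
    } else {                       // region 0
      double inv = 1.0 / det;
      s *= inv;
      t *= inv;
    }
  } else {
    if (s < 0.0) {                 // region 2
      double tmp0 = B + Dd, tmp1 = C + E;
      if (tmp1 > tmp0) {
        double numer = tmp1 - tmp0;
        double denom = A - 2.0*B + C;
        s = (numer >= denom ? 1.0 : numer / denom);
        t = 1.0 - s;
      } else {
        s = 0.0;
        t = (tmp1 <= 0.0 ? 1.0 : (E >= 0.0 ? 0.0 : -E / C));
      }
    } else if (t < 0.0) {          // region 6
      double tmp0 = B + E, tmp1 = A + Dd;
      if (tmp1 > tmp0) {
        double numer = tmp1 - tmp0;
        double denom = A - 2.0*B + C;
        t = (numer >= denom ? 1.0 : numer / denom);
        s = 1.0 - t;
      } else {
        t = 0.0;
        s = (tmp1 <= 0.0 ? 1.0 : (Dd >= 0.0 ? 0.0 : -Dd / A));
      }
    } else {                       // region 1
      double numer = (C + E) - (B + Dd);
      if (numer <= 0.0) {
        s = 0.0;
      } else {
        double denom = A - 2.0*B + C;
        s = (numer >= denom ? 1.0 : numer / denom);
      }
      t = 1.0 - s;
    }
  }
  double q2 = A*s*s + 2.0*B*s*t + C*t*t + 2.0*Dd*s + 2.0*E*t + F;
  return q2 < 0.0 ? 0.0 : q2;
}

// [[Rcpp::export]]
NumericVector cpp_point_mesh_distance(NumericMatrix points,
                                      NumericMatrix verts,
                                      IntegerMatrix faces0) {
  const int np = points.nrow();
  const int nf = faces0.nrow();
  if (np == 0 || nf == 0) stop("empty mesh");

  // Precompute face vertex pointers, centroids and circumscribing radii
  // for a cheap lower-bound prune.
  std::vector<double> cx(nf), cy(nf), cz(nf), rad(nf);
  std::vector<int> ia(nf), ib(nf), ic(nf);
  for (int f = 0; f < nf; ++f) {
    ia[f] = faces0(f, 0);
    ib[f] = faces0(f, 1);
    ic[f] = faces0(f, 2);
    double ax = verts(ia[f], 0), ay = verts(ia[f], 1), az = verts(ia[f], 2);
    double bx = verts(ib[f], 0), by = verts(ib[f], 1), bz = verts(ib[f], 2);
    double ccx = verts(ic[f], 0), ccy = verts(ic[f], 1), ccz = verts(ic[f], 2);
    cx[f] = (ax + bx + ccx) / 3.0;
    cy[f] = (ay + by + ccy) / 3.0;
    cz[f] = (az + bz + ccz) / 3.0;
    double r2 = 0.0;
    double d2a = (ax-cx[f])*(ax-cx[f]) + (ay-cy[f])*(ay-cy[f]) + (az-cz[f])*(az-cz[f]);
    double d2b = (bx-cx[f])*(bx-cx[f]) + (by-cy[f])*(by-cy[f]) + (bz-cz[f])*(bz-cz[f]);
    double d2c = (ccx-cx[f])*(ccx-cx[f]) + (ccy-cy[f])*(ccy-cy[f]) + (ccz-cz[f])*(ccz-cz[f]);
    r2 = std::max(d2a, std::max(d2b, d2c));
    rad[f] = std::sqrt(r2);
  }

  NumericVector out(np);
  double a[3], b[3], c[3], p[3];
  for (int i = 0; i < np; ++i) {
    p[0] = points(i, 0); p[1] = points(i, 1); p[2] = points(i, 2);
    double best = std::numeric_limits<double>::infinity();
    double best_d = std::numeric_limits<double>::infinity();
    for (int f = 0; f < nf; ++f) {
      double dx = p[0] - cx[f], dy = p[1] - cy[f], dz = p[2] - cz[f];
      double dc = std::sqrt(dx*dx + dy*dy + dz*dz);
      double lb = dc - rad[f];
      if (lb > 0.0 && lb >= best_d) continue;
      a[0] = verts(ia[f], 0); a[1] = verts(ia[f], 1); a[2] = verts(ia[f], 2);
      b[0] = verts(ib[f], 0); b[1] = verts(ib[f], 1); b[2] = verts(ib[f], 2);
      c[0] = verts(ic[f], 0); c[1] = verts(ic[f], 1); c[2] = verts(ic[f], 2);
      double d2 = point_tri_dist2(p, a, b, c);
      if (d2 < best) {
        best = d2;
        best_d = std::sqrt(best);
      }
    }
    out[i] = best_d;
  }
  return out;
}
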