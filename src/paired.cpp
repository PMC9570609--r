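#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Pairing test: the reflection of center p across plane (n, d, anchor) must
// land inside a foreground voxel. Voxel boxes are half-open
// (lower-inclusive), so containment reduces to floor-binning of the
// reflected point. `s2` is twice the signed distance of p to the d = 0 plane
// and `d2` is twice d, hoisted by the callers.
static inline bool reflected_hit(double px, double py, double pz,
                                 const double *n, double s2, double d2,
                                 const int *dim, const double *inv_sp,
                                 const double *origin,
                                 const unsigned char *occ) {
  double t = s2 + d2;
  double vx = (px - t * n[0] - origin[0]) * inv_sp[0];
  double vy = (py - t * n[1] - origin[1]) * inv_sp[1];
  double vz = (pz - t * n[2] - origin[2]) * inv_sp[2];
  if (vx < 0 || vy < 0 || vz < 0 ||
      vx >= dim[0] || vy >= dim[1] || vz >= dim[2])
    return false;
  // non-negative, so cast truncation equals floor
  int ix = (int)vx, iy = (int)vy, iz = (int)vz;
  return occ[ix + (size_t)dim[0] * (iy + (size_t)dim[1] * iz)] != 0;
}

static std::vector<unsigned char> pack_occ(const IntegerVector &occ) {
  std::vector<unsigned char> out(occ.size());
  const int *p = INTEGER(occ);
  for (R_xlen_t i = 0; i < occ.size(); ++i) out[i] = (unsigned char)p[i];
  return out;
}

// [[Rcpp::export]]
int cpp_paired_eval(NumericMatrix centers, IntegerVector occ, IntegerVector dim,
                    NumericVector spacing, NumericVector origin,
                    NumericVector normal, double d, NumericVector anchor) {
  const int N = centers.nrow();
  const double n[3] = {normal[0], normal[1], normal[2]};
  const double a[3] = {anchor[0], anchor[1], anchor[2]};
  const double o[3] = {origin[0], origin[1], origin[2]};
  const double inv_sp[3] = {1.0 / spacing[0], 1.0 / spacing[1], 1.0 / spacing[2]};
  const int dm[3] = {dim[0], dim[1], dim[2]};
  std::vector<unsigned char> oc = pack_occ(occ);
  const double *cx = &centers(0, 0), *cy = &centers(0, 1), *cz = &centers(0, 2);
  const double d2 = 2.0 * d;
  int paired = 0;
  for (int i = 0; i < N; ++i) {
    double s = n[0] * (cx[i] - a[0]) + n[1] * (cy[i] - a[1]) + n[2] * (cz[i] - a[2]);
    if (reflected_hit(cx[i], cy[i], cz[i], n, 2.0 * s, d2,
                      dm, inv_sp, o, oc.data()))
      ++paired;
  }
  return paired;
}

// Coarse scan over a list of orientations x a uniform d-grid (multiples of
// d_step). For each orientation the d-grid is clipped to the foreground's
// signed-distance span (+- one d_step): planes outside the span pair nothing,
// so the clip cannot change the maximizer. Because the paired count is
// sharply peaked in d (the peak is narrower than one voxel), each
// orientation's best coarse d is then polished by a halving line search down
// to d_tol before orientations are compared. Returns the coarse evaluations
// and the per-orientation polished optima.
// [[Rcpp::export]]
List cpp_sr_scan(NumericMatrix centers, IntegerVector occ, IntegerVector dim,
                 NumericVector spacing, NumericVector origin,
                 NumericVector anchor, NumericVector phis,
                 NumericVector thetas, double d_step, double d_max,
                 double d_tol) {
  const int N = centers.nrow();
  const int K = phis.size();
  const double a[3] = {anchor[0], anchor[1], anchor[2]};
  const double o[3] = {origin[0], origin[1], origin[2]};
  const double inv_sp[3] = {1.0 / spacing[0], 1.0 / spacing[1], 1.0 / spacing[2]};
  const int dm[3] = {dim[0], dim[1], dim[2]};
  std::vector<unsigned char> oc = pack_occ(occ);
  const unsigned char *ocp = oc.data();
  const double *cx = &centers(0, 0), *cy = &centers(0, 1), *cz = &centers(0, 2);

  std::vector<double> s2(N);
  std::vector<double> out_phi, out_theta, out_d;
  std::vector<int> out_paired;
  NumericVector best_phi(K), best_theta(K), best_d(K);
  IntegerVector best_paired(K);

  for (int k = 0; k < K; ++k) {
    double phi = phis[k], theta = thetas[k];
    double n[3] = {std::sin(phi) * std::cos(theta),
                   std::sin(phi) * std::sin(theta),
                   std::cos(phi)};
    double smin = R_PosInf, smax = R_NegInf;
    for (int i = 0; i < N; ++i) {
      double v = n[0] * (cx[i] - a[0]) + n[1] * (cy[i] - a[1]) + n[2] * (cz[i] - a[2]);
      s2[i] = 2.0 * v;
      if (v < smin) smin = v;
      if (v > smax) smax = v;
    }
    // plane passes through signed distance -d; clip to span
    double dlo = std::max(-d_max, -smax - d_step);
    double dhi = std::min(d_max, -smin + d_step);
    long klo = (long)std::ceil(dlo / d_step - 1e-9);
    long khi = (long)std::floor(dhi / d_step + 1e-9);
    double bd = 0.0;
    int bp = -1;
    for (long kd = klo; kd <= khi; ++kd) {
      double d = kd * d_step;
      double d2 = 2.0 * d;
      int paired = 0;
      for (int i = 0; i < N; ++i) {
        if (reflected_hit(cx[i], cy[i], cz[i], n, s2[i], d2,
                          dm, inv_sp, o, ocp))
          ++paired;
      }
      out_phi.push_back(phi);
      out_theta.push_back(theta);
      out_d.push_back(d);
      out_paired.push_back(paired);
      if (paired > bp || (paired == bp && std::fabs(d) < std::fabs(bd))) {
        bp = paired;
        bd = d;
      }
    }
    // halving line search in d around the coarse argmax
    double step = d_step / 2.0;
    while (step >= d_tol && bp >= 0) {
      bool moved = true;
      while (moved) {
        moved = false;
        for (int sgn = -1; sgn <= 1; sgn += 2) {
          double d = bd + sgn * step;
          if (std::fabs(d) > d_max) continue;
          double d2 = 2.0 * d;
          int paired = 0;
          for (int i = 0; i < N; ++i) {
            if (reflected_hit(cx[i], cy[i], cz[i], n, s2[i], d2,
                              dm, inv_sp, o, ocp))
              ++paired;
          }
          if (paired > bp ||
              (paired == bp && std::fabs(d) < std::fabs(bd) - 1e-12)) {
            bp = paired;
            bd = d;
            moved = true;
          }
        }
      }
      step /= 2.0;
    }
    best_phi[k] = phi;
    best_theta[k] = theta;
    best_d[k] = bd;
    best_paired[k] = bp;
    if (k % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
      _["coarse"] = DataFrame::create(_["phi"] = out_phi,
                                      _["theta"] = out_theta,
                                      _["d"] = out_d,
                                      _["paired"] = out_paired),
      _["best"] = DataFrame::create(_["phi"] = best_phi,
                                    _["theta"] = best_theta,
                                    _["d"] = best_d,
                                    _["paired"] = best_paired));
}
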