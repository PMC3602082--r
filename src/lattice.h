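// Mass-spring lattice mechanics: square lattice of mass points with direct
// active springs and diagonal passive springs, relaxed to elastostatic
// equilibrium by damped position-Verlet iteration. The damping force in a
// spring is capped at a configured fraction of that spring's Hooke force
// whenever it would exceed it, which keeps the iteration well conditioned.
#ifndef CARDIOMECH_LATTICE_H
#define CARDIOMECH_LATTICE_H

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include "nhs.h"

struct MechView {
  int n_pts;
  double* pos;      // 2*n (x0,y0,x1,y1,...)
  double* prev;     // Verlet history
  double* vel;      // central-difference velocity estimate
  int n_act;
  const int* ia; const int* ja; const double* l0a;
  int n_pas;
  const int* ip; const int* jp; const double* l0p;
  const int* fixed_mask;      // 1 = boundary-fixed
  int n_quads;
  const int* quads;           // 4*n_quads, ccw vertex order fixed at build
  const int* spring_quads;    // 2*n_act, adjacent quad indices (-1 = none)
  double k;                   // active spring stiffness
  double k_ratio;             // passive/active stiffness ratio
  double c;                   // damping coefficient (active springs)
  double cap_frac;            // damping cap as fraction of Hooke force
  int cap_on;
  double mass;                // mass per point
  double contract_coef;       // Ta -> force scale (1/(rho*l0))
  double dt_mech;
  double s0;                  // reference quad area (l0a^2)
};

// accumulate spring forces into f (2*n); Ta per active spring; returns max
// squared force magnitude over free points; damping uses current vel estimate
inline double lattice_forces(const MechView& M, const double* ta_act, double* f) {
  const int n = M.n_pts;
  for (int i = 0; i < 2 * n; ++i) f[i] = 0.0;
  for (int s = 0; s < M.n_act; ++s) {
    const int i = M.ia[s], j = M.ja[s];
    const double dx = M.pos[2 * j] - M.pos[2 * i];
    const double dy = M.pos[2 * j + 1] - M.pos[2 * i + 1];
    const double len = std::sqrt(dx * dx + dy * dy);
    if (len <= 1e-12) Rcpp::stop("zero-length active spring %d-%d", i, j);
    const double ux = dx / len, uy = dy / len;
    const double fh = M.k * (len - M.l0a[s]);
    const double ldot = (M.vel[2 * j] - M.vel[2 * i]) * ux +
                        (M.vel[2 * j + 1] - M.vel[2 * i + 1]) * uy;
    double fd = M.c * ldot;
    if (M.cap_on) {
      const double cap = M.cap_frac * std::fabs(fh);
      if (std::fabs(fd) > cap) fd = (fd > 0.0 ? cap : -cap);
    }
    const double fc = (ta_act != 0) ? ta_act[s] * M.contract_coef : 0.0;
    const double ftot = fh + fd + fc;
    f[2 * i]     += ftot * ux;  f[2 * i + 1] += ftot * uy;
    f[2 * j]     -= ftot * ux;  f[2 * j + 1] -= ftot * uy;
  }
  const double kp = M.k * M.k_ratio, cp = M.c * M.k_ratio;
  for (int s = 0; s < M.n_pas; ++s) {
    const int i = M.ip[s], j = M.jp[s];
    const double dx = M.pos[2 * j] - M.pos[2 * i];
    const double dy = M.pos[2 * j + 1] - M.pos[2 * i + 1];
    const double len = std::sqrt(dx * dx + dy * dy);
    if (len <= 1e-12) Rcpp::stop("zero-length passive spring %d-%d", i, j);
    const double ux = dx / len, uy = dy / len;
    const double fh = kp * (len - M.l0p[s]);
    const double ldot = (M.vel[2 * j] - M.vel[2 * i]) * ux +
                        (M.vel[2 * j + 1] - M.vel[2 * i + 1]) * uy;
    double fd = cp * ldot;
    if (M.cap_on) {
      const double cap = M.cap_frac * std::fabs(fh);
      if (std::fabs(fd) > cap) fd = (fd > 0.0 ? cap : -cap);
    }
    const double ftot = fh + fd;
    f[2 * i]     += ftot * ux;  f[2 * i + 1] += ftot * uy;
    f[2 * j]     -= ftot * ux;  f[2 * j + 1] -= ftot * uy;
  }
  double fmax2 = 0.0;
  for (int i = 0; i < n; ++i) {
    if (M.fixed_mask[i]) continue;
    const double f2 = f[2 * i] * f[2 * i] + f[2 * i + 1] * f[2 * i + 1];
    if (f2 > fmax2) fmax2 = f2;
  }
  return fmax2;
}

// one position-Verlet update of the free points; first = 1 uses the
// half-acceleration start formula (zero initial pseudo-velocity)
inline void verlet_update(MechView& M, const double* f, int first) {
  const double dt = M.dt_mech, dt2 = dt * dt, inv2dt = 1.0 / (2.0 * dt);
  for (int i = 0; i < M.n_pts; ++i) {
    if (M.fixed_mask[i]) {
      M.prev[2 * i] = M.pos[2 * i]; M.prev[2 * i + 1] = M.pos[2 * i + 1];
      M.vel[2 * i] = 0.0; M.vel[2 * i + 1] = 0.0;
      continue;
    }
    for (int d = 0; d < 2; ++d) {
      const double a = f[2 * i + d] / M.mass;
      const double x = M.pos[2 * i + d];
      double xnew;
      if (first) xnew = x + 0.5 * a * dt2;
      else       xnew = 2.0 * x - M.prev[2 * i + d] + a * dt2;
      M.vel[2 * i + d] = (xnew - M.prev[2 * i + d]) * inv2dt;
      M.prev[2 * i + d] = x;
      M.pos[2 * i + d] = xnew;
    }
  }
}

// signed shoelace area of quad q (positive for the build-time ccw ordering)
inline double quad_area(const MechView& M, int q) {
  const int* v = M.quads + 4 * q;
  double a = 0.0;
  for (int e = 0; e < 4; ++e) {
    const int p1 = v[e], p2 = v[(e + 1) % 4];
    a += M.pos[2 * p1] * M.pos[2 * p2 + 1] - M.pos[2 * p2] * M.pos[2 * p1 + 1];
  }
  return 0.5 * a;
}

inline void lambda_quads(const MechView& M, double* lam) {
  for (int q = 0; q < M.n_quads; ++q) {
    const double S = quad_area(M, q);
    if (S <= 0.0) Rcpp::stop("mesh tangling: non-positive area in quad %d", q);
    lam[q] = std::sqrt(S / M.s0);
  }
}

// damped Verlet relaxation with the update method: T_lv (already scaled by
// the velocity factor at the committed stretch rate) is frozen per quad; the
// filament-overlap length factor g_len is re-evaluated each iteration from
// the trial stretch of each active spring itself (the sarcomere lies along
// the fibre direction, and coupling the length feedback to the spring's own
// length suppresses the area-hourglass mode that a quad-area length factor
// cannot see). lam_out receives the converged per-quad area-based lambda
// used by the stretch-activated current. Returns iterations used, or -1 on
// max_iter exceeded.
inline int verlet_relax_nhs(MechView& M, const NhsParams& NP,
                            const double* t_lv_h, int reset_history,
                            double f_th, int max_iter,
                            double* lam_out, std::vector<double>& scratch) {
  const int nq = M.n_quads, na = M.n_act;
  scratch.resize(2 * M.n_pts + nq + na);
  double* f = scratch.data();
  double* ta_q = f + 2 * M.n_pts;
  double* ta_s = ta_q + nq;
  const double fth2 = f_th * f_th;
  // the pseudo-dynamics keep their momentum across electrical steps
  // (continuous dynamic relaxation); a reset is done only at run start
  if (reset_history)
    for (int i = 0; i < 2 * M.n_pts; ++i) { M.prev[i] = M.pos[i]; M.vel[i] = 0.0; }
  int it = 0;
  for (; it <= max_iter; ++it) {
    lambda_quads(M, lam_out);
    for (int s = 0; s < na; ++s) {
      const int q1 = M.spring_quads[2 * s], q2 = M.spring_quads[2 * s + 1];
      double tlvh;
      if (q1 >= 0 && q2 >= 0) tlvh = 0.5 * (t_lv_h[q1] + t_lv_h[q2]);
      else if (q1 >= 0) tlvh = t_lv_h[q1];
      else if (q2 >= 0) tlvh = t_lv_h[q2];
      else tlvh = 0.0;
      const int i = M.ia[s], j = M.ja[s];
      const double dx = M.pos[2 * j] - M.pos[2 * i];
      const double dy = M.pos[2 * j + 1] - M.pos[2 * i + 1];
      const double lam_s = std::sqrt(dx * dx + dy * dy) / M.l0a[s];
      const double ta = tlvh * nhs_g_len(NP, lam_s);
      ta_s[s] = ta > 0.0 ? ta : 0.0;
    }
    (void)ta_q;
    const double fmax2 = lattice_forces(M, ta_s, f);
    if (fmax2 < fth2) return it;
    if (it == max_iter) break;
    verlet_update(M, f, reset_history && it == 0);
  }
  return -1;
}

#endif
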