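// Niederer-Hunter-Smith (2006) active-tension model with human adjustments.
// State per mechanical element: z (bound crossbridge / available actin-site
// fraction), CaTRPN (troponin-C calcium occupancy, mM), Q1..Q3 (fading-memory
// components), lambda (committed pseudo sarcomere length at the last electrical
// step). The length factor g_len and velocity factor h_vel are pure algebraic
// functions re-evaluated inside the mechanical iteration ("update method").
#ifndef CARDIOMECH_NHS_H
#define CARDIOMECH_NHS_H

#include <Rcpp.h>
#include <cmath>

enum NhsIdx { NH_Z = 0, NH_CATRPN, NH_Q1, NH_Q2, NH_Q3, NH_LAMBDA };
#define NHS_NSTATE 6

struct NhsParams {
  double k_on, k_ref_off, gamma_trpn, ca_trpn_max;
  double alpha_0, alpha_r1, alpha_r2, n_rel, K_z, n_hill, ca_50ref, z_p;
  double beta_0, beta_1, T_ref, a_xb;
  double A1, A2, A3, alph1, alph2, alph3;
  double lambda_lo, lambda_hi;   // validity clip for length laws
  double k_off_min_frac;         // floor on tension-dependent unbinding rate
  double dlam_tau;               // smoothing time (ms) of the stretch-rate
                                 // estimate entering the fading memory
  // derived linearization constants of the nonlinear release term about z_p
  double K1, K2;

  void finish() {
    const double zn = std::pow(z_p, n_rel);
    const double Kn = std::pow(K_z, n_rel);
    K1 = alpha_r2 * n_rel * std::pow(z_p, n_rel - 1.0) * Kn / ((zn + Kn) * (zn + Kn));
    K2 = alpha_r2 * zn / (zn + Kn) * (1.0 - n_rel * Kn / (zn + Kn));
  }
};

inline NhsParams nhs_params_from_vector(const Rcpp::NumericVector& p) {
  Rcpp::CharacterVector nm = p.names();
  std::map<std::string, double> m;
  for (int i = 0; i < p.size(); ++i) m[std::string(nm[i])] = p[i];
  auto get = [&](const char* k) {
    auto it = m.find(k);
    if (it == m.end()) Rcpp::stop("NHS parameter '%s' missing", k);
    return it->second;
  };
  NhsParams P;
  P.k_on = get("k_on"); P.k_ref_off = get("k_ref_off");
  P.gamma_trpn = get("gamma_trpn"); P.ca_trpn_max = get("ca_trpn_max");
  P.alpha_0 = get("alpha_0"); P.alpha_r1 = get("alpha_r1"); P.alpha_r2 = get("alpha_r2");
  P.n_rel = get("n_rel"); P.K_z = get("K_z"); P.n_hill = get("n_hill");
  P.ca_50ref = get("ca_50ref"); P.z_p = get("z_p");
  P.beta_0 = get("beta_0"); P.beta_1 = get("beta_1");
  P.T_ref = get("T_ref"); P.a_xb = get("a_xb");
  P.A1 = get("A1"); P.A2 = get("A2"); P.A3 = get("A3");
  P.alph1 = get("alpha_1"); P.alph2 = get("alpha_2"); P.alph3 = get("alpha_3");
  P.lambda_lo = get("lambda_lo"); P.lambda_hi = get("lambda_hi");
  P.k_off_min_frac = get("k_off_min_frac");
  P.dlam_tau = get("dlam_tau");
  P.finish();
  return P;
}

inline double nhs_clip_lambda(const NhsParams& P, double lam) {
  if (lam < P.lambda_lo) return P.lambda_lo;
  if (lam > P.lambda_hi) return P.lambda_hi;
  return lam;
}

// filament-overlap (length) factor
inline double nhs_g_len(const NhsParams& P, double lam) {
  const double g = 1.0 + P.beta_0 * (nhs_clip_lambda(P, lam) - 1.0);
  return g > 0.0 ? g : 0.0;
}

// fading-memory (velocity) factor from the summed memory terms
inline double nhs_h_vel(const NhsParams& P, double Q) {
  if (Q < 0.0) return (P.a_xb * Q + 1.0) / (1.0 - Q);
  return (1.0 + (P.a_xb + 2.0) * Q) / (1.0 + Q);
}

inline double nhs_ca_trpn_50(const NhsParams& P, double lam) {
  const double lc = nhs_clip_lambda(P, lam);
  const double ca50 = P.ca_50ref * (1.0 + P.beta_1 * (lc - 1.0));
  return P.ca_trpn_max * ca50 /
         (ca50 + (P.k_ref_off / P.k_on) *
                     (1.0 - (1.0 + P.beta_0 * (lc - 1.0)) * 0.5 / P.gamma_trpn));
}

inline double nhs_z_max(const NhsParams& P, double lam) {
  const double k = std::pow(P.ca_trpn_max / nhs_ca_trpn_50(P, lam), P.n_hill);
  return (P.alpha_0 * k - P.K2) / (P.alpha_r1 + P.K1 + P.alpha_0 * k);
}

// length/velocity independent tension (held fixed across the mechanics loop)
inline double nhs_t_lv(const NhsParams& P, double z, double lam) {
  double t = P.T_ref * z / nhs_z_max(P, lam);
  return t > 0.0 ? t : 0.0;
}

// advance z and CaTRPN by one explicit Euler step on the electrical clock;
// ta_total is the committed total tension (tension-dependent troponin
// unbinding rate)
inline void nhs_step_ztrpn(const NhsParams& P, double* s, double ca_i,
                           double lam, double ta_total, double dt) {
  const double catrpn50 = nhs_ca_trpn_50(P, lam);
  const double zn = std::pow(s[NH_Z], P.n_rel);
  const double Kn = std::pow(P.K_z, P.n_rel);
  const double act = P.alpha_0 * std::pow(s[NH_CATRPN] / catrpn50, P.n_hill);
  const double dz = act * (1.0 - s[NH_Z]) - P.alpha_r1 * s[NH_Z] -
                    P.alpha_r2 * zn / (zn + Kn);
  double k_off = P.k_ref_off * (1.0 - ta_total / (P.gamma_trpn * P.T_ref));
  const double k_off_min = P.k_off_min_frac * P.k_ref_off;
  if (k_off < k_off_min) k_off = k_off_min;
  const double dtrpn = P.k_on * ca_i * (P.ca_trpn_max - s[NH_CATRPN]) -
                       k_off * s[NH_CATRPN];
  s[NH_Z] += dt * dz;
  s[NH_CATRPN] += dt * dtrpn;
}

// advance the fading-memory terms with a given stretch rate
inline void nhs_advance_q(const NhsParams& P, double* s, double dlam_dt, double dt) {
  s[NH_Q1] += dt * (P.A1 * dlam_dt - P.alph1 * s[NH_Q1]);
  s[NH_Q2] += dt * (P.A2 * dlam_dt - P.alph2 * s[NH_Q2]);
  s[NH_Q3] += dt * (P.A3 * dlam_dt - P.alph3 * s[NH_Q3]);
}

// full single-element commit (z, troponin, fading memory, lambda)
inline void nhs_commit_step(const NhsParams& P, double* s, double ca_i,
                            double lam, double dlam_dt, double ta_total,
                            double dt) {
  nhs_step_ztrpn(P, s, ca_i, s[NH_LAMBDA], ta_total, dt);
  nhs_advance_q(P, s, dlam_dt, dt);
  s[NH_LAMBDA] = lam;
}

// total tension with trial-configuration scaling factors (update method);
// qtrial = Q after a one-step trial advance at the trial dlam/dt
inline double nhs_total_tension_trial(const NhsParams& P, const double* s,
                                      double t_lv, double lam_trial,
                                      double dlam_trial, double dt) {
  const double g = nhs_g_len(P, lam_trial);
  const double q1 = s[NH_Q1] + dt * (P.A1 * dlam_trial - P.alph1 * s[NH_Q1]);
  const double q2 = s[NH_Q2] + dt * (P.A2 * dlam_trial - P.alph2 * s[NH_Q2]);
  const double q3 = s[NH_Q3] + dt * (P.A3 * dlam_trial - P.alph3 * s[NH_Q3]);
  const double h = nhs_h_vel(P, q1 + q2 + q3);
  double ta = t_lv * g * h;
  return ta > 0.0 ? ta : 0.0;
}

#endif
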