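// Exported computational kernels: TP06 single-cell integration, NHS tension,
// lattice statics/relaxation, and the coupled electromechanical sheet loop.
#include <Rcpp.h>
#include <vector>
#include <cstring>
#include "tp06.h"
#include "nhs.h"
#include "lattice.h"

using namespace Rcpp;

// ---------------------------------------------------------------- TP06 cell

static void check_state_finite(const NumericVector& s) {
  CharacterVector nm = s.names();
  for (int i = 0; i < s.size(); ++i)
    if (!R_finite(s[i]))
      stop("non-finite state entry '%s'", nm.size() ? std::string(nm[i]) : std::to_string(i));
}

// [[Rcpp::export]]
List cpp_tp06_currents(NumericVector state, NumericVector params,
                       double i_sac, double i_stim) {
  check_state_finite(state);
  Tp06Params P = tp06_params_from_vector(params);
  Tp06Currents c;
  tp06_currents_eval(REAL(state), P, i_sac, i_stim, c);
  return List::create(
      _["I_Na"] = c.INa, _["I_CaL"] = c.ICaL, _["I_to"] = c.Ito,
      _["I_Kr"] = c.IKr, _["I_Ks"] = c.IKs, _["I_K1"] = c.IK1,
      _["I_NaK"] = c.INaK, _["I_NaCa"] = c.INaCa, _["I_pCa"] = c.IpCa,
      _["I_pK"] = c.IpK, _["I_bCa"] = c.IbCa, _["I_bNa"] = c.IbNa,
      _["I_sac"] = c.Isac, _["I_stim"] = c.Istim, _["I_tot"] = c.Itot);
}

// [[Rcpp::export]]
NumericVector cpp_tp06_step(NumericVector state, NumericVector params,
                            double i_sac, double i_stim, double dt) {
  check_state_finite(state);
  Tp06Params P = tp06_params_from_vector(params);
  NumericVector out = clone(state);
  tp06_step_inplace(REAL(out), P, i_sac, i_stim, dt, 0.0);
  return out;
}

struct StimSchedule {
  std::vector<double> t0, dur, amp;
  bool active(double t, int e) const { return t >= t0[e] && t < t0[e] + dur[e]; }
  double current(double t) const {
    double s = 0.0;
    for (size_t e = 0; e < t0.size(); ++e) if (active(t, e)) s += amp[e];
    return s;
  }
};

inline double sac_current(double lam, double V, double gs, double es,
                          double lmax, int rect) {
  double frac = (lam - 1.0) / (lmax - 1.0);
  if (rect && frac < 0.0) frac = 0.0;
  if (frac > 1.0) frac = 1.0;
  if (frac < -1.0) frac = -1.0;
  return gs * frac * (V - es);
}

// Single cell (optionally with NHS tension under a prescribed stretch course).
// lambda_t: length 1 (constant) or n_steps (per-step prescribed stretch).
// [[Rcpp::export]]
List cpp_run_cell(NumericVector state, NumericVector params,
                  NumericVector nhs_state, NumericVector nhs_params, int with_nhs,
                  double dt, int n_steps, double t_start,
                  NumericVector lambda_t,
                  double gs, double es, double lambda_max, int sac_rect,
                  NumericVector stim_t0, NumericVector stim_dur, NumericVector stim_amp,
                  NumericVector vset_t, NumericVector vset_v,
                  int record_every) {
  check_state_finite(state);
  Tp06Params P = tp06_params_from_vector(params);
  NhsParams NP;
  std::vector<double> ns(NHS_NSTATE, 0.0);
  if (with_nhs) {
    NP = nhs_params_from_vector(nhs_params);
    for (int i = 0; i < NHS_NSTATE; ++i) ns[i] = nhs_state[i];
  }
  std::vector<double> y(state.begin(), state.end());
  StimSchedule st;
  st.t0.assign(stim_t0.begin(), stim_t0.end());
  st.dur.assign(stim_dur.begin(), stim_dur.end());
  st.amp.assign(stim_amp.begin(), stim_amp.end());
  std::vector<bool> vdone(vset_t.size(), false);
  const bool lam_var = lambda_t.size() > 1;

  const int n_rec = (record_every > 0) ? (n_steps / record_every + 1) : 0;
  NumericMatrix trace(n_rec, 7);
  colnames(trace) = CharacterVector::create("t", "V", "Ca_i", "lambda",
                                            "I_sac", "T_lv", "Ta");
  int rec = 0;
  double lam_prev = lam_var ? lambda_t[0] : lambda_t[0];
  double ta_comm = 0.0, t_lv = 0.0, dlam_smooth = 0.0;

  for (int s = 0; s <= n_steps; ++s) {
    const double t = t_start + s * dt;
    const double lam = lam_var ? lambda_t[std::min(s, n_steps - 1)] : lambda_t[0];
    if (with_nhs) t_lv = nhs_t_lv(NP, ns[NH_Z], lam);
    if (record_every > 0 && s % record_every == 0 && rec < n_rec) {
      const double isac_now = sac_current(lam, y[TP_V], gs, es, lambda_max, sac_rect);
      trace(rec, 0) = t; trace(rec, 1) = y[TP_V]; trace(rec, 2) = y[TP_CAI];
      trace(rec, 3) = lam; trace(rec, 4) = isac_now;
      trace(rec, 5) = t_lv; trace(rec, 6) = ta_comm;
      ++rec;
    }
    if (s == n_steps) break;
    for (int e = 0; e < vset_t.size(); ++e)
      if (!vdone[e] && t >= vset_t[e] - 1e-9) { y[TP_V] = vset_v[e]; vdone[e] = true; }
    const double isac = sac_current(lam, y[TP_V], gs, es, lambda_max, sac_rect);
    const double istim = st.current(t);
    tp06_step_inplace(y.data(), P, isac, istim, dt, 0.0);
    if (with_nhs) {
      const double wsm = (NP.dlam_tau > 0.0) ? dt / NP.dlam_tau : 1.0;
      dlam_smooth += wsm * ((lam - lam_prev) / dt - dlam_smooth);
      nhs_commit_step(NP, ns.data(), y[TP_CAI], lam, dlam_smooth, ta_comm, dt);
      t_lv = nhs_t_lv(NP, ns[NH_Z], lam);
      const double g = nhs_g_len(NP, lam);
      const double h = nhs_h_vel(NP, ns[NH_Q1] + ns[NH_Q2] + ns[NH_Q3]);
      ta_comm = std::max(0.0, t_lv * g * h);
    }
    lam_prev = lam;
  }
  NumericVector out_state(y.begin(), y.end());
  out_state.names() = state.names();
  NumericVector out_nhs(ns.begin(), ns.end());
  return List::create(_["state"] = out_state, _["nhs_state"] = out_nhs,
                      _["trace"] = trace, _["t_end"] = t_start + n_steps * dt);
}

// --------------------------------------------------------------- lattice ops

struct MechData {
  std::vector<double> pos, prev, vel, l0a, l0p;
  std::vector<int> ia, ja, ip, jp, fixedm, quads, squads;
  MechView V;
};

static void mech_from_list(const List& mesh, MechData& M) {
  NumericMatrix pos = mesh["pos"], prev = mesh["prev"], vel = mesh["vel"];
  const int n = pos.nrow();
  M.pos.resize(2 * n); M.prev.resize(2 * n); M.vel.resize(2 * n);
  for (int i = 0; i < n; ++i) {
    M.pos[2 * i] = pos(i, 0); M.pos[2 * i + 1] = pos(i, 1);
    M.prev[2 * i] = prev(i, 0); M.prev[2 * i + 1] = prev(i, 1);
    M.vel[2 * i] = vel(i, 0); M.vel[2 * i + 1] = vel(i, 1);
  }
  IntegerMatrix act = mesh["active"], pas = mesh["passive"];
  NumericVector l0a = mesh["l0_active"], l0p = mesh["l0_passive"];
  const int na = act.nrow(), np = pas.nrow();
  M.ia.resize(na); M.ja.resize(na); M.l0a.assign(l0a.begin(), l0a.end());
  for (int s = 0; s < na; ++s) { M.ia[s] = act(s, 0) - 1; M.ja[s] = act(s, 1) - 1; }
  M.ip.resize(np); M.jp.resize(np); M.l0p.assign(l0p.begin(), l0p.end());
  for (int s = 0; s < np; ++s) { M.ip[s] = pas(s, 0) - 1; M.jp[s] = pas(s, 1) - 1; }
  IntegerVector fx = mesh["fixed"];
  M.fixedm.assign(fx.begin(), fx.end());
  IntegerMatrix qd = mesh["quads"];
  const int nq = qd.nrow();
  M.quads.resize(4 * nq);
  for (int q = 0; q < nq; ++q)
    for (int e = 0; e < 4; ++e) M.quads[4 * q + e] = qd(q, e) - 1;
  IntegerMatrix sq = mesh["spring_quads"];
  M.squads.resize(2 * na);
  for (int s = 0; s < na; ++s) {
    M.squads[2 * s] = sq(s, 0) - 1;     // 0 in R marks "none" -> -1
    M.squads[2 * s + 1] = sq(s, 1) - 1;
  }
  MechView& W = M.V;
  W.n_pts = n; W.pos = M.pos.data(); W.prev = M.prev.data(); W.vel = M.vel.data();
  W.n_act = na; W.ia = M.ia.data(); W.ja = M.ja.data(); W.l0a = M.l0a.data();
  W.n_pas = np; W.ip = M.ip.data(); W.jp = M.jp.data(); W.l0p = M.l0p.data();
  W.fixed_mask = M.fixedm.data();
  W.n_quads = nq; W.quads = M.quads.data(); W.spring_quads = M.squads.data();
  W.k = as<double>(mesh["k"]); W.k_ratio = as<double>(mesh["k_ratio"]);
  W.c = as<double>(mesh["c"]); W.cap_frac = as<double>(mesh["cap_frac"]);
  W.cap_on = as<int>(mesh["cap_on"]); W.mass = as<double>(mesh["mass"]);
  W.contract_coef = as<double>(mesh["contract_coef"]);
  W.dt_mech = as<double>(mesh["dt_mech"]); W.s0 = as<double>(mesh["s0"]);
}

static List mech_positions_out(const MechData& M) {
  const int n = M.V.n_pts;
  NumericMatrix pos(n, 2), prev(n, 2), vel(n, 2);
  for (int i = 0; i < n; ++i) {
    pos(i, 0) = M.pos[2 * i]; pos(i, 1) = M.pos[2 * i + 1];
    prev(i, 0) = M.prev[2 * i]; prev(i, 1) = M.prev[2 * i + 1];
    vel(i, 0) = M.vel[2 * i]; vel(i, 1) = M.vel[2 * i + 1];
  }
  return List::create(_["pos"] = pos, _["prev"] = prev, _["vel"] = vel);
}

// [[Rcpp::export]]
List cpp_lattice_forces(List mesh, NumericVector ta_active) {
  MechData M; mech_from_list(mesh, M);
  if ((int)ta_active.size() != M.V.n_act)
    stop("ta_active must have one entry per active spring");
  for (double ta : ta_active) if (ta < 0) stop("negative active tension");
  std::vector<double> f(2 * M.V.n_pts);
  double fmax2 = lattice_forces(M.V, REAL(ta_active), f.data());
  NumericMatrix F(M.V.n_pts, 2);
  for (int i = 0; i < M.V.n_pts; ++i) { F(i, 0) = f[2 * i]; F(i, 1) = f[2 * i + 1]; }
  return List::create(_["forces"] = F, _["fmax"] = std::sqrt(fmax2));
}

// Relaxation under a frozen per-spring active tension (no update method);
// used by the R-level verlet_relax and by oracle tests.
// [[Rcpp::export]]
List cpp_verlet_relax_fixed(List mesh, NumericVector ta_active, double f_th,
                            int max_iter, int reset_history, int keep_residuals) {
  MechData M; mech_from_list(mesh, M);
  std::vector<double> f(2 * M.V.n_pts);
  std::vector<double> resid;
  if (reset_history)
    for (int i = 0; i < 2 * M.V.n_pts; ++i) { M.prev[i] = M.pos[i]; M.vel[i] = 0.0; }
  const double* ta = ta_active.size() ? REAL(ta_active) : 0;
  const double fth2 = f_th * f_th;
  int it = 0; bool converged = false;
  for (; it <= max_iter; ++it) {
    const double fmax2 = lattice_forces(M.V, ta, f.data());
    if (keep_residuals) resid.push_back(std::sqrt(fmax2));
    if (fmax2 < fth2) { converged = true; break; }
    if (it == max_iter) break;
    verlet_update(M.V, f.data(), reset_history && it == 0);
  }
  List out = mech_positions_out(M);
  out["iterations"] = it;
  out["converged"] = converged;
  out["residuals"] = NumericVector(resid.begin(), resid.end());
  return out;
}

// One raw Verlet iteration (for R-level Ta providers and oscillator oracles).
// [[Rcpp::export]]
List cpp_verlet_step(List mesh, NumericVector ta_active, int first) {
  MechData M; mech_from_list(mesh, M);
  std::vector<double> f(2 * M.V.n_pts);
  const double* ta = ta_active.size() ? REAL(ta_active) : 0;
  double fmax2 = lattice_forces(M.V, ta, f.data());
  verlet_update(M.V, f.data(), first);
  List out = mech_positions_out(M);
  out["fmax"] = std::sqrt(fmax2);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_area_elements(List mesh) {
  MechData M; mech_from_list(mesh, M);
  NumericVector S(M.V.n_quads);
  for (int q = 0; q < M.V.n_quads; ++q) {
    const double a = quad_area(M.V, q);
    if (a <= 0.0) stop("mesh tangling: non-positive area in quad %d", q + 1);
    S[q] = a;
  }
  return S;
}

// virial (pairwise) Cauchy stress over the lattice, per unit deformed area.
// Direct springs are weighted by half their adjacent-cell count so the sum
// is consistent with the covered area (each cell carries 4 half-shared
// direct springs and 2 whole diagonals); without the weight the boundary
// rows bias the stress by O(1/n).
// [[Rcpp::export]]
NumericMatrix cpp_virial_stress(List mesh, NumericVector ta_active, double area_def) {
  MechData M; mech_from_list(mesh, M);
  const double* ta = ta_active.size() ? REAL(ta_active) : 0;
  double sxx = 0, syy = 0, sxy = 0;
  const MechView& W = M.V;
  for (int s = 0; s < W.n_act; ++s) {
    const int i = W.ia[s], j = W.ja[s];
    const double dx = W.pos[2 * j] - W.pos[2 * i];
    const double dy = W.pos[2 * j + 1] - W.pos[2 * i + 1];
    const double len = std::sqrt(dx * dx + dy * dy);
    double fs = W.k * (len - W.l0a[s]);
    if (ta) fs += ta[s] * W.contract_coef;
    const int nadj = (W.spring_quads[2 * s] >= 0) + (W.spring_quads[2 * s + 1] >= 0);
    const double w = (nadj > 0) ? 0.5 * nadj : 0.0;
    fs *= w;
    sxx += fs / len * dx * dx; syy += fs / len * dy * dy; sxy += fs / len * dx * dy;
  }
  for (int s = 0; s < W.n_pas; ++s) {
    const int i = W.ip[s], j = W.jp[s];
    const double dx = W.pos[2 * j] - W.pos[2 * i];
    const double dy = W.pos[2 * j + 1] - W.pos[2 * i + 1];
    const double len = std::sqrt(dx * dx + dy * dy);
    const double fs = W.k * W.k_ratio * (len - W.l0p[s]);
    sxx += fs / len * dx * dx; syy += fs / len * dy * dy; sxy += fs / len * dx * dy;
  }
  NumericMatrix S(2, 2);
  S(0, 0) = sxx / area_def; S(1, 1) = syy / area_def;
  S(0, 1) = S(1, 0) = sxy / area_def;
  return S;
}

// [[Rcpp::export]]
NumericVector cpp_nhs_step(NumericVector nhs_state, NumericVector nhs_params,
                           double ca_i, double lambda, double dlambda_dt,
                           double ta_committed, double dt) {
  NhsParams NP = nhs_params_from_vector(nhs_params);
  std::vector<double> s(nhs_state.begin(), nhs_state.end());
  nhs_commit_step(NP, s.data(), ca_i, lambda, dlambda_dt, ta_committed, dt);
  return NumericVector(s.begin(), s.end());
}

// ------------------------------------------------------------- coupled sheet

// bilinear interpolation of per-quad lambda (quad centers) to electrical nodes
static void lambda_to_nodes(const double* lam_q, int nqx, int nqy,
                            int nx, int ny, double* lam_n) {
  for (int iy = 0; iy < ny; ++iy) {
    double v = (iy - 1.0) / 2.0;          // quad-center index space
    int b = (int)std::floor(v);
    double fy = v - b;
    if (b < 0) { b = 0; fy = 0.0; }
    if (b >= nqy - 1) { b = nqy - 1; fy = 0.0; }
    const int b2 = (b + 1 < nqy) ? b + 1 : b;
    for (int ix = 0; ix < nx; ++ix) {
      double u = (ix - 1.0) / 2.0;
      int a = (int)std::floor(u);
      double fx = u - a;
      if (a < 0) { a = 0; fx = 0.0; }
      if (a >= nqx - 1) { a = nqx - 1; fx = 0.0; }
      const int a2 = (a + 1 < nqx) ? a + 1 : a;
      const double l00 = lam_q[b * nqx + a],  l10 = lam_q[b * nqx + a2];
      const double l01 = lam_q[b2 * nqx + a], l11 = lam_q[b2 * nqx + a2];
      lam_n[iy * nx + ix] = (1 - fy) * ((1 - fx) * l00 + fx * l10) +
                            fy * ((1 - fx) * l01 + fx * l11);
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_lambda_field(NumericVector lam_q, int nqx, int nqy,
                               int nx, int ny) {
  if (lam_q.size() != nqx * nqy) stop("lambda/quad grid inconsistency");
  NumericVector out(nx * ny);
  lambda_to_nodes(REAL(lam_q), nqx, nqy, nx, ny, REAL(out));
  return out;
}

// [[Rcpp::export]]
List cpp_run_sheet(NumericVector Vin, NumericMatrix Yin,
                   NumericVector params,
                   int nx, int ny, double hs, double Dcoef, double dt,
                   int n_steps, double t_start,
                   int mode,                       // 0 fixed-lambda, 1 contracting
                   NumericVector lambda_in,        // length N fixed field (mode 0)
                   double gs, double es, double lambda_max, int sac_rect,
                   List mech, NumericVector nhs_params, NumericMatrix nhs_in,
                   NumericVector ta_comm_in, NumericVector dlam_comm_in,
                   IntegerVector quad_ca_node,     // 1-based elec node per quad
                   List stim_nodes, NumericVector stim_t0, NumericVector stim_dur,
                   NumericVector stim_amp,
                   List vset_nodes, NumericVector vset_t, NumericVector vset_v,
                   IntegerVector probes, IntegerVector probe_quads,
                   int record_every, int frame_every,
                   double f_th, int max_iter_mech, int reaction_on,
                   int use_lut) {
  const int N = nx * ny;
  if (Vin.size() != N) stop("V field size mismatch");
  Tp06Params P = tp06_params_from_vector(params);
  Tp06Tables T;
  if (use_lut && reaction_on) T.build(P, dt);
  const double rdx2 = Dcoef / (hs * hs);

  std::vector<double> V(Vin.begin(), Vin.end()), Vnew(N);
  std::vector<double> Y(Yin.begin(), Yin.end());   // 18 x N column-major
  std::vector<double> lam_node(N, 1.0), istim(N, 0.0);
  if (lambda_in.size() == N) std::copy(lambda_in.begin(), lambda_in.end(), lam_node.begin());
  else if (lambda_in.size() == 1) std::fill(lam_node.begin(), lam_node.end(), lambda_in[0]);

  // mechanics
  MechData M;
  NhsParams NP;
  std::vector<double> nhs, t_lv, tlv_h, lam_q, ta_comm, dlam_comm, scratch;
  int nqx = 0, nqy = 0, nq = 0;
  if (mode == 1) {
    mech_from_list(mech, M);
    NP = nhs_params_from_vector(nhs_params);
    nq = M.V.n_quads;
    nqx = as<int>(mech["nqx"]); nqy = as<int>(mech["nqy"]);
    if (nqx * nqy != nq) stop("quad grid inconsistency");
    nhs.assign(nhs_in.begin(), nhs_in.end());
    if ((int)nhs.size() != NHS_NSTATE * nq) stop("nhs state size mismatch");
    t_lv.resize(nq); tlv_h.resize(nq); lam_q.resize(nq);
    if (ta_comm_in.size() == nq) ta_comm.assign(ta_comm_in.begin(), ta_comm_in.end());
    else ta_comm.assign(nq, 0.0);
    if (dlam_comm_in.size() == nq) dlam_comm.assign(dlam_comm_in.begin(), dlam_comm_in.end());
    else dlam_comm.assign(nq, 0.0);
    // lambda field from the incoming mesh configuration
    lambda_quads(M.V, lam_q.data());
    lambda_to_nodes(lam_q.data(), nqx, nqy, nx, ny, lam_node.data());
  }

  // stimuli
  const int n_ev = stim_t0.size();
  std::vector<std::vector<int>> ev_nodes(n_ev);
  for (int e = 0; e < n_ev; ++e) {
    IntegerVector nd = stim_nodes[e];
    ev_nodes[e].assign(nd.begin(), nd.end());
    for (int& i : ev_nodes[e]) --i;
  }
  std::vector<bool> ev_on(n_ev, false);
  const int n_vev = vset_t.size();
  std::vector<std::vector<int>> vev_nodes(n_vev);
  for (int e = 0; e < n_vev; ++e) {
    IntegerVector nd = vset_nodes[e];
    vev_nodes[e].assign(nd.begin(), nd.end());
    for (int& i : vev_nodes[e]) --i;
  }
  std::vector<bool> vev_done(n_vev, false);

  // recording
  const int n_pr = probes.size();
  const int n_rec = (record_every > 0 && n_pr > 0) ? n_steps / record_every + 1 : 0;
  NumericMatrix trace(n_rec * (n_pr > 0 ? n_pr : 1), 8);
  colnames(trace) = CharacterVector::create("probe", "t", "V", "Ca_i", "lambda",
                                            "I_sac", "Ta", "T_lv");
  int rec_row = 0;
  const int n_fr = (frame_every > 0) ? n_steps / frame_every + 1 : 0;
  NumericMatrix frames(n_fr > 0 ? N : 0, n_fr);
  NumericVector frame_times(n_fr);
  int fr = 0;
  IntegerVector mech_iters(mode == 1 ? n_steps : 0);

  auto record_probes = [&](double t) {
    for (int p = 0; p < n_pr; ++p) {
      const int nd = probes[p] - 1;
      const double lam = lam_node[nd];
      trace(rec_row, 0) = p + 1; trace(rec_row, 1) = t;
      trace(rec_row, 2) = V[nd]; trace(rec_row, 3) = Y[18 * nd + (TP_CAI - 1)];
      trace(rec_row, 4) = lam;
      trace(rec_row, 5) = sac_current(lam, V[nd], gs, es, lambda_max, sac_rect);
      if (mode == 1 && probe_quads.size() == n_pr && probe_quads[p] > 0) {
        trace(rec_row, 6) = ta_comm[probe_quads[p] - 1];
        trace(rec_row, 7) = t_lv[probe_quads[p] - 1];
      } else { trace(rec_row, 6) = 0.0; trace(rec_row, 7) = 0.0; }
      ++rec_row;
    }
  };

  // Y is stored 18 x N (column per node): per-node state assembled as
  // y[0]=V, y[1..18]=Y[,node] (TP06 ordering without V)
  double y[TP06_NSTATE];
  std::vector<double> ca_q(nq > 0 ? nq : 1);

  for (int s = 0; s <= n_steps; ++s) {
    const double t = t_start + s * dt;
    if (record_every > 0 && n_pr > 0 && s % record_every == 0 && rec_row + n_pr <= trace.nrow())
      record_probes(t);
    if (frame_every > 0 && s % frame_every == 0 && fr < n_fr) {
      for (int i = 0; i < N; ++i) frames(i, fr) = V[i];
      frame_times[fr] = t;
      ++fr;
    }
    if (s == n_steps) break;
    if (s % 2000 == 0) Rcpp::checkUserInterrupt();

    // stimulus bookkeeping
    bool changed = false;
    for (int e = 0; e < n_ev; ++e) {
      const bool on = (t >= stim_t0[e] && t < stim_t0[e] + stim_dur[e]);
      if (on != ev_on[e]) { ev_on[e] = on; changed = true; }
    }
    if (changed) {
      std::fill(istim.begin(), istim.end(), 0.0);
      for (int e = 0; e < n_ev; ++e)
        if (ev_on[e]) for (int nd : ev_nodes[e]) istim[nd] += stim_amp[e];
    }
    for (int e = 0; e < n_vev; ++e)
      if (!vev_done[e] && t >= vset_t[e] - 1e-9) {
        for (int nd : vev_nodes[e]) V[nd] = vset_v[e];
        vev_done[e] = true;
      }

    // electrical update (explicit Euler, 5-point Laplacian, no-flux mirror)
    for (int iy = 0; iy < ny; ++iy) {
      // zero-flux boundary: ghost node mirrors the boundary node itself,
      // which conserves the spatial mean of V exactly
      const int il = (iy > 0) ? iy - 1 : 0;
      const int ir = (iy < ny - 1) ? iy + 1 : ny - 1;
      for (int ix = 0; ix < nx; ++ix) {
        const int jl = (ix > 0) ? ix - 1 : 0;
        const int jr = (ix < nx - 1) ? ix + 1 : nx - 1;
        const int nd = iy * nx + ix;
        const double lap = rdx2 * (V[iy * nx + jl] + V[iy * nx + jr] +
                                   V[il * nx + ix] + V[ir * nx + ix] - 4.0 * V[nd]);
        if (!reaction_on) { Vnew[nd] = V[nd] + dt * lap; continue; }
        y[TP_V] = V[nd];
        double* yc = &Y[18 * nd];
        std::memcpy(y + 1, yc, 18 * sizeof(double));
        const double isac = sac_current(lam_node[nd], V[nd], gs, es, lambda_max, sac_rect);
        if (use_lut) tp06_step_lut(y, P, T, isac, istim[nd], dt, lap);
        else tp06_step_inplace(y, P, isac, istim[nd], dt, lap);
        Vnew[nd] = y[TP_V];
        std::memcpy(yc, y + 1, 18 * sizeof(double));
      }
    }
    std::swap(V, Vnew);

    // mechanics update after every electrical step
    if (mode == 1) {
      for (int q = 0; q < nq; ++q)
        ca_q[q] = Y[18 * (quad_ca_node[q] - 1) + (TP_CAI - 1)];
      for (int q = 0; q < nq; ++q) {
        double* sN = &nhs[NHS_NSTATE * q];
        // z, troponin and fading memory advance on the electrical clock at
        // the committed configuration and stretch rate; inside the
        // relaxation only the length factor is re-evaluated (the velocity
        // factor changes negligibly over one electrical step and feeding the
        // trial stretch rate back into it makes the explicit iteration stiff)
        nhs_step_ztrpn(NP, sN, ca_q[q], sN[NH_LAMBDA], ta_comm[q], dt);
        nhs_advance_q(NP, sN, dlam_comm[q], dt);
        const double h = nhs_h_vel(NP, sN[NH_Q1] + sN[NH_Q2] + sN[NH_Q3]);
        t_lv[q] = nhs_t_lv(NP, sN[NH_Z], sN[NH_LAMBDA]);
        tlv_h[q] = t_lv[q] * h;
      }
      const int it = verlet_relax_nhs(M.V, NP, tlv_h.data(), 1,
                                      f_th, max_iter_mech, lam_q.data(), scratch);
      if (it < 0) stop("mechanical relaxation failed to converge at t=%.3f ms", t);
      mech_iters[s] = it;
      const double wsm = (NP.dlam_tau > 0.0) ? dt / NP.dlam_tau : 1.0;
      for (int q = 0; q < nq; ++q) {
        double* sN = &nhs[NHS_NSTATE * q];
        // smoothed stretch-rate estimate for the fading memory (the memory
        // kernel's own time constants are far longer than one electrical
        // step, and the raw per-step rate couples unstably to the tension)
        const double dlam_raw = (lam_q[q] - sN[NH_LAMBDA]) / dt;
        dlam_comm[q] += wsm * (dlam_raw - dlam_comm[q]);
        // committed total tension equals the converged loop tension
        const double g = nhs_g_len(NP, lam_q[q]);
        ta_comm[q] = std::max(0.0, tlv_h[q] * g);
        sN[NH_LAMBDA] = lam_q[q];
      }
      lambda_to_nodes(lam_q.data(), nqx, nqy, nx, ny, lam_node.data());
    }
  }

  List out = List::create(
      _["V"] = NumericVector(V.begin(), V.end()),
      _["Y"] = NumericMatrix(18, N, Y.begin()),
      _["lambda_field"] = NumericVector(lam_node.begin(), lam_node.end()),
      _["trace"] = trace, _["frames"] = frames, _["frame_times"] = frame_times,
      _["mech_iters"] = mech_iters, _["t_end"] = t_start + n_steps * dt);
  if (mode == 1) {
    out["mech"] = mech_positions_out(M);
    out["nhs_state"] = NumericMatrix(NHS_NSTATE, nq, nhs.begin());
    out["ta_comm"] = NumericVector(ta_comm.begin(), ta_comm.end());
    out["dlam_comm"] = NumericVector(dlam_comm.begin(), dlam_comm.end());
  }
  return out;
}
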