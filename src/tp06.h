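// TP06 human epicardial ventricular myocyte model (ten Tusscher & Panfilov 2006).
// State layout and integration scheme follow the published reference formulation:
// explicit Euler for V, gates and ion fluxes, with the standard analytic
// steady-state buffer solve for the three calcium pools.
#ifndef CARDIOMECH_TP06_H
#define CARDIOMECH_TP06_H

#include <Rcpp.h>
#include <cmath>

enum Tp06Idx {
  TP_V = 0, TP_M, TP_H, TP_J, TP_D, TP_F, TP_F2, TP_FCASS,
  TP_R, TP_S, TP_XR1, TP_XR2, TP_XS,
  TP_NAI, TP_KI, TP_CAI, TP_CASR, TP_CASS, TP_RBAR
};
#define TP06_NSTATE 19

struct Tp06Params {
  double R, T, F, Cm;
  double Vc, Vsr, Vss;
  double Ko, Nao, Cao;
  double Gna, GK1, Gto, GKr, GKs, GCaL, GbNa, GbCa, GpCa, KpCa, GpK;
  double pKNa;
  double knak, KmK, KmNa;
  double knaca, KmNai, KmCa, ksat, nnaca, alpha_naca;
  double Vmaxup, Kup, Vrel, k1p, k2p, k3, k4, EC, maxsr, minsr, Vleak, Vxfer;
  double Bufc, Kbufc, Bufsr, Kbufsr, Bufss, Kbufss;
  int rush_larsen;           // 0 = forward Euler gates (default), 1 = exponential gate update
  // derived
  double RTONF, invVcF, invVcF2, invVssF2;

  void finish() {
    RTONF  = R * T / F;
    invVcF  = 1.0 / (Vc * F);
    invVcF2 = 1.0 / (2.0 * Vc * F);
    invVssF2 = 1.0 / (2.0 * Vss * F);
  }
};

inline Tp06Params tp06_params_from_vector(const Rcpp::NumericVector& p) {
  Rcpp::CharacterVector nm = p.names();
  std::map<std::string, double> m;
  for (int i = 0; i < p.size(); ++i) m[std::string(nm[i])] = p[i];
  auto get = [&](const char* k) {
    auto it = m.find(k);
    if (it == m.end()) Rcpp::stop("TP06 parameter '%s' missing", k);
    return it->second;
  };
  Tp06Params P;
  P.R = get("R_gas"); P.T = get("T_temp"); P.F = get("F_faraday"); P.Cm = get("Cm");
  P.Vc = get("V_c"); P.Vsr = get("V_sr"); P.Vss = get("V_ss");
  P.Ko = get("K_o"); P.Nao = get("Na_o"); P.Cao = get("Ca_o");
  P.Gna = get("G_Na"); P.GK1 = get("G_K1"); P.Gto = get("G_to");
  P.GKr = get("G_Kr"); P.GKs = get("G_Ks"); P.GCaL = get("G_CaL");
  P.GbNa = get("G_bNa"); P.GbCa = get("G_bCa");
  P.GpCa = get("G_pCa"); P.KpCa = get("K_pCa"); P.GpK = get("G_pK");
  P.pKNa = get("p_KNa");
  P.knak = get("P_NaK"); P.KmK = get("K_mK"); P.KmNa = get("K_mNa");
  P.knaca = get("k_NaCa"); P.KmNai = get("K_mNai"); P.KmCa = get("K_mCa");
  P.ksat = get("k_sat"); P.nnaca = get("gamma_NaCa"); P.alpha_naca = get("alpha_NaCa");
  P.Vmaxup = get("Vmax_up"); P.Kup = get("K_up"); P.Vrel = get("V_rel");
  P.k1p = get("k1_prime"); P.k2p = get("k2_prime"); P.k3 = get("k3"); P.k4 = get("k4");
  P.EC = get("EC"); P.maxsr = get("max_sr"); P.minsr = get("min_sr");
  P.Vleak = get("V_leak"); P.Vxfer = get("V_xfer");
  P.Bufc = get("Buf_c"); P.Kbufc = get("K_bufc");
  P.Bufsr = get("Buf_sr"); P.Kbufsr = get("K_bufsr");
  P.Bufss = get("Buf_ss"); P.Kbufss = get("K_bufss");
  P.rush_larsen = m.count("rush_larsen") ? (int)m["rush_larsen"] : 0;
  P.finish();
  return P;
}

struct Tp06Currents {
  double INa, ICaL, Ito, IKr, IKs, IK1, INaK, INaCa, IpCa, IpK, IbCa, IbNa;
  double Isac, Istim, Itot;
};

// Membrane currents at the instant described by state y (no state change).
inline void tp06_currents_eval(const double* y, const Tp06Params& P,
                               double i_sac, double i_stim, Tp06Currents& c) {
  const double V = y[TP_V];
  const double Nai = y[TP_NAI], Ki = y[TP_KI], Cai = y[TP_CAI], CaSS = y[TP_CASS];
  const double Ek  = P.RTONF * std::log(P.Ko / Ki);
  const double Ena = P.RTONF * std::log(P.Nao / Nai);
  const double Eks = P.RTONF * std::log((P.Ko + P.pKNa * P.Nao) / (Ki + P.pKNa * Nai));
  const double Eca = 0.5 * P.RTONF * std::log(P.Cao / Cai);
  const double FRT = 1.0 / P.RTONF;

  const double Ak1 = 0.1 / (1.0 + std::exp(0.06 * (V - Ek - 200.0)));
  const double Bk1 = (3.0 * std::exp(0.0002 * (V - Ek + 100.0)) +
                      std::exp(0.1 * (V - Ek - 10.0))) /
                     (1.0 + std::exp(-0.5 * (V - Ek)));
  const double rec_iK1 = Ak1 / (Ak1 + Bk1);
  const double rec_iNaK = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V * FRT) +
                                 0.0353 * std::exp(-V * FRT));
  const double rec_ipK = 1.0 / (1.0 + std::exp((25.0 - V) / 5.98));

  c.INa = P.Gna * y[TP_M] * y[TP_M] * y[TP_M] * y[TP_H] * y[TP_J] * (V - Ena);
  {
    // removable singularity at V = 15 mV: nudge off the exact point
    double vshift = V - 15.0;
    if (std::fabs(vshift) < 1e-6) vshift = (vshift >= 0.0) ? 1e-6 : -1e-6;
    const double e2 = std::exp(2.0 * vshift * FRT);
    c.ICaL = P.GCaL * y[TP_D] * y[TP_F] * y[TP_F2] * y[TP_FCASS] *
             4.0 * vshift * P.F * FRT * (0.25 * e2 * CaSS - P.Cao) / (e2 - 1.0);
  }
  c.Ito = P.Gto * y[TP_R] * y[TP_S] * (V - Ek);
  c.IKr = P.GKr * std::sqrt(P.Ko / 5.4) * y[TP_XR1] * y[TP_XR2] * (V - Ek);
  c.IKs = P.GKs * y[TP_XS] * y[TP_XS] * (V - Eks);
  c.IK1 = P.GK1 * rec_iK1 * (V - Ek);
  c.INaCa = P.knaca * (1.0 / (P.KmNai * P.KmNai * P.KmNai + P.Nao * P.Nao * P.Nao)) *
            (1.0 / (P.KmCa + P.Cao)) *
            (1.0 / (1.0 + P.ksat * std::exp((P.nnaca - 1.0) * V * FRT))) *
            (std::exp(P.nnaca * V * FRT) * Nai * Nai * Nai * P.Cao -
             std::exp((P.nnaca - 1.0) * V * FRT) * P.Nao * P.Nao * P.Nao * Cai *
             P.alpha_naca);
  c.INaK = P.knak * (P.Ko / (P.Ko + P.KmK)) * (Nai / (Nai + P.KmNa)) * rec_iNaK;
  c.IpCa = P.GpCa * Cai / (P.KpCa + Cai);
  c.IpK  = P.GpK * rec_ipK * (V - Ek);
  c.IbNa = P.GbNa * (V - Ena);
  c.IbCa = P.GbCa * (V - Eca);
  c.Isac = i_sac;
  c.Istim = i_stim;
  c.Itot = c.INa + c.ICaL + c.Ito + c.IKr + c.IKs + c.IK1 + c.INaK + c.INaCa +
           c.IpCa + c.IpK + c.IbCa + c.IbNa + c.Isac + c.Istim;
}

// One explicit Euler step of gates, concentrations and V (V gets dvdt_extra added,
// e.g. the diffusion term in tissue). Advances y in place. Returns total current.
inline double tp06_step_inplace(double* y, const Tp06Params& P,
                                double i_sac, double i_stim,
                                double dt, double dvdt_extra) {
  Tp06Currents c;
  tp06_currents_eval(y, P, i_sac, i_stim, c);
  const double V = y[TP_V];
  const double CaSS_old = y[TP_CASS];

  // --- calcium subsystem (uses currents at time t) ---
  {
    double Cai = y[TP_CAI], CaSR = y[TP_CASR], CaSS = y[TP_CASS], RR = y[TP_RBAR];
    const double kCaSR = P.maxsr - (P.maxsr - P.minsr) /
                         (1.0 + (P.EC / CaSR) * (P.EC / CaSR));
    const double k1 = P.k1p / kCaSR;
    const double k2 = P.k2p * kCaSR;
    const double dRR = P.k4 * (1.0 - RR) - k2 * CaSS * RR;
    y[TP_RBAR] = RR + dt * dRR;
    const double OO = k1 * CaSS * CaSS * y[TP_RBAR] / (P.k3 + k1 * CaSS * CaSS);
    const double Irel = P.Vrel * OO * (CaSR - CaSS);
    const double Ileak = P.Vleak * (CaSR - Cai);
    const double Iup = P.Vmaxup / (1.0 + (P.Kup * P.Kup) / (Cai * Cai));
    const double Ixfer = P.Vxfer * (CaSS - Cai);

    const double CaCSQN = P.Bufsr * CaSR / (CaSR + P.Kbufsr);
    const double dCaSR = dt * (Iup - Irel - Ileak);
    const double bjsr = P.Bufsr - CaCSQN - dCaSR - CaSR + P.Kbufsr;
    const double cjsr = P.Kbufsr * (CaCSQN + dCaSR + CaSR);
    y[TP_CASR] = (std::sqrt(bjsr * bjsr + 4.0 * cjsr) - bjsr) / 2.0;

    const double CaSSBuf = P.Bufss * CaSS / (CaSS + P.Kbufss);
    const double dCaSS = dt * (-Ixfer * (P.Vc / P.Vss) + Irel * (P.Vsr / P.Vss) +
                               (-c.ICaL * P.invVssF2 * P.Cm));
    const double bcss = P.Bufss - CaSSBuf - dCaSS - CaSS + P.Kbufss;
    const double ccss = P.Kbufss * (CaSSBuf + dCaSS + CaSS);
    y[TP_CASS] = (std::sqrt(bcss * bcss + 4.0 * ccss) - bcss) / 2.0;

    const double CaBuf = P.Bufc * Cai / (Cai + P.Kbufc);
    const double dCai = dt * ((-(c.IbCa + c.IpCa - 2.0 * c.INaCa) * P.invVcF2 * P.Cm) -
                              (Iup - Ileak) * (P.Vsr / P.Vc) + Ixfer);
    const double bc = P.Bufc - CaBuf - dCai - Cai + P.Kbufc;
    const double cc = P.Kbufc * (CaBuf + dCai + Cai);
    y[TP_CAI] = (std::sqrt(bc * bc + 4.0 * cc) - bc) / 2.0;
  }

  y[TP_NAI] += dt * (-(c.INa + c.IbNa + 3.0 * c.INaK + 3.0 * c.INaCa) * P.invVcF * P.Cm);
  y[TP_KI]  += dt * (-(c.Istim + c.IK1 + c.Ito + c.IKr + c.IKs - 2.0 * c.INaK + c.IpK) *
                     P.invVcF * P.Cm);

  // --- gating variables (rates evaluated at V(t), CaSS(t)) ---
  double ginf[13], gtau[13];
  {
    const double AM = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
    const double BM = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
                      0.10 / (1.0 + std::exp((V - 50.0) / 200.0));
    gtau[0] = AM * BM;
    { double t = 1.0 + std::exp((-56.86 - V) / 9.03); ginf[0] = 1.0 / (t * t); }
    { double t = 1.0 + std::exp((V + 71.55) / 7.43); ginf[1] = 1.0 / (t * t); }
    ginf[2] = ginf[1];
    if (V >= -40.0) {
      const double BH = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
      gtau[1] = 1.0 / BH;
      const double BJ = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
      gtau[2] = 1.0 / BJ;
    } else {
      const double AH = 0.057 * std::exp(-(V + 80.0) / 6.8);
      const double BH = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
      gtau[1] = 1.0 / (AH + BH);
      const double AJ = (-2.5428e4 * std::exp(0.2444 * V) -
                         6.948e-6 * std::exp(-0.04391 * V)) * (V + 37.78) /
                        (1.0 + std::exp(0.311 * (V + 79.23)));
      const double BJ = 0.02424 * std::exp(-0.01052 * V) /
                        (1.0 + std::exp(-0.1378 * (V + 40.14)));
      gtau[2] = 1.0 / (AJ + BJ);
    }
    ginf[3] = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
    {
      const double Ad = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
      const double Bd = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
      const double Cd = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
      gtau[3] = Ad * Bd + Cd;
    }
    ginf[4] = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
    gtau[4] = 1102.5 * std::exp(-(V + 27.0) * (V + 27.0) / 225.0) +
              200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
              180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0;
    ginf[5] = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
    gtau[5] = 562.0 * std::exp(-(V + 27.0) * (V + 27.0) / 240.0) +
              31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
              80.0 / (1.0 + std::exp((V + 30.0) / 10.0));
    {
      const double c2 = (CaSS_old / 0.05) * (CaSS_old / 0.05);
      ginf[6] = 0.6 / (1.0 + c2) + 0.4;
      gtau[6] = 80.0 / (1.0 + c2) + 2.0;
    }
    ginf[7] = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));       // r (epi)
    gtau[7] = 9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
    ginf[8] = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));       // s (epi)
    gtau[8] = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
              5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
    ginf[9] = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
    gtau[9] = (450.0 / (1.0 + std::exp((-45.0 - V) / 10.0))) *
              (6.0 / (1.0 + std::exp((V + 30.0) / 11.5)));
    ginf[10] = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
    gtau[10] = (3.0 / (1.0 + std::exp((-60.0 - V) / 20.0))) *
               (1.12 / (1.0 + std::exp((V - 60.0) / 20.0)));
    ginf[11] = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
    gtau[11] = (1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0))) *
               (1.0 / (1.0 + std::exp((V - 35.0) / 15.0))) + 80.0;
    ginf[12] = ginf[0]; gtau[12] = gtau[0]; // placeholder slot (unused)
  }
  static const int gidx[12] = {TP_M, TP_H, TP_J, TP_D, TP_F, TP_F2, TP_FCASS,
                               TP_R, TP_S, TP_XR1, TP_XR2, TP_XS};
  if (P.rush_larsen) {
    for (int g = 0; g < 12; ++g)
      y[gidx[g]] = ginf[g] - (ginf[g] - y[gidx[g]]) * std::exp(-dt / gtau[g]);
  } else {
    for (int g = 0; g < 12; ++g)
      y[gidx[g]] += dt * (ginf[g] - y[gidx[g]]) / gtau[g];
  }

  y[TP_V] = V + dt * (dvdt_extra - c.Itot);
  return c.Itot;
}

// ---------------------------------------------------------------------------
// Voltage lookup tables for the tissue kernel. All voltage-dependent gate
// targets (steady state + exponential/Euler update factors for the run's dt)
// and current coefficients are tabulated on a fine V grid with linear
// interpolation; the inward-rectifier coefficient is tabulated on V - E_K.
// Cell-level entry points keep the direct analytic path.
// ---------------------------------------------------------------------------

#define TP06_LUT_NCOL 31

struct Tp06Tables {
  double vmin, vmax, dv, inv_dv;
  double xmin, xmax;                 // V - E_K axis for I_K1
  int n, nk;
  std::vector<double> tab;           // n rows x TP06_LUT_NCOL (row-major)
  std::vector<double> k1tab;         // rec_iK1 on V - E_K axis
  // columns: 0..11 gate_inf (m h j d f f2 r s xr1 xr2 xs -) ; 12..23 gate_fac
  // 24 rec_iNaK, 25 rec_ipK, 26 icalf1 (CaSS coef), 27 icalf2 (Cao coef),
  // 28 naca1, 29 naca2, 30 spare

  void build(const Tp06Params& P, double dt) {
    vmin = -120.0; vmax = 90.0; dv = 0.02; inv_dv = 1.0 / dv;
    n = (int)std::floor((vmax - vmin) / dv) + 2;
    tab.assign((size_t)n * TP06_LUT_NCOL, 0.0);
    const double FRT = P.F / (P.R * P.T);
    for (int i = 0; i < n; ++i) {
      const double V = vmin + i * dv;
      double* r = &tab[(size_t)i * TP06_LUT_NCOL];
      double ginf[12], gtau[12];
      const double AM = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
      const double BM = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
                        0.10 / (1.0 + std::exp((V - 50.0) / 200.0));
      gtau[0] = AM * BM;
      { double t = 1.0 + std::exp((-56.86 - V) / 9.03); ginf[0] = 1.0 / (t * t); }
      { double t = 1.0 + std::exp((V + 71.55) / 7.43); ginf[1] = 1.0 / (t * t); }
      ginf[2] = ginf[1];
      if (V >= -40.0) {
        gtau[1] = 0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)) / 0.77;
        gtau[2] = (1.0 + std::exp(-0.1 * (V + 32.0))) / (0.6 * std::exp(0.057 * V));
      } else {
        const double AH = 0.057 * std::exp(-(V + 80.0) / 6.8);
        const double BH = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
        gtau[1] = 1.0 / (AH + BH);
        const double AJ = (-2.5428e4 * std::exp(0.2444 * V) -
                           6.948e-6 * std::exp(-0.04391 * V)) * (V + 37.78) /
                          (1.0 + std::exp(0.311 * (V + 79.23)));
        const double BJ = 0.02424 * std::exp(-0.01052 * V) /
                          (1.0 + std::exp(-0.1378 * (V + 40.14)));
        gtau[2] = 1.0 / (AJ + BJ);
      }
      ginf[3] = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
      {
        const double Ad = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
        const double Bd = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
        const double Cd = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
        gtau[3] = Ad * Bd + Cd;
      }
      ginf[4] = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
      gtau[4] = 1102.5 * std::exp(-(V + 27.0) * (V + 27.0) / 225.0) +
                200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
                180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0;
      ginf[5] = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
      gtau[5] = 562.0 * std::exp(-(V + 27.0) * (V + 27.0) / 240.0) +
                31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
                80.0 / (1.0 + std::exp((V + 30.0) / 10.0));
      ginf[6] = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
      gtau[6] = 9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
      ginf[7] = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
      gtau[7] = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
                5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
      ginf[8] = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
      gtau[8] = (450.0 / (1.0 + std::exp((-45.0 - V) / 10.0))) *
                (6.0 / (1.0 + std::exp((V + 30.0) / 11.5)));
      ginf[9] = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
      gtau[9] = (3.0 / (1.0 + std::exp((-60.0 - V) / 20.0))) *
                (1.12 / (1.0 + std::exp((V - 60.0) / 20.0)));
      ginf[10] = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
      gtau[10] = (1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0))) *
                 (1.0 / (1.0 + std::exp((V - 35.0) / 15.0))) + 80.0;
      ginf[11] = 0.0; gtau[11] = 1.0;
      for (int g = 0; g < 12; ++g) {
        r[g] = ginf[g];
        r[12 + g] = P.rush_larsen ? std::exp(-dt / gtau[g]) : dt / gtau[g];
      }
      r[24] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V * FRT) +
                     0.0353 * std::exp(-V * FRT));
      r[25] = 1.0 / (1.0 + std::exp((25.0 - V) / 5.98));
      double vshift = V - 15.0;
      if (std::fabs(vshift) < 1e-6) vshift = (vshift >= 0.0) ? 1e-6 : -1e-6;
      const double e2 = std::exp(2.0 * vshift * FRT);
      const double base = 4.0 * vshift * P.F * FRT / (e2 - 1.0);
      r[26] = base * 0.25 * e2;
      r[27] = base;
      const double A = P.knaca /
          ((P.KmNai * P.KmNai * P.KmNai + P.Nao * P.Nao * P.Nao) *
           (P.KmCa + P.Cao) *
           (1.0 + P.ksat * std::exp((P.nnaca - 1.0) * V * FRT)));
      r[28] = A * std::exp(P.nnaca * V * FRT) * P.Cao;
      r[29] = A * std::exp((P.nnaca - 1.0) * V * FRT) * P.Nao * P.Nao * P.Nao *
              P.alpha_naca;
      r[30] = 0.0;
    }
    xmin = -60.0; xmax = 220.0;
    nk = (int)std::floor((xmax - xmin) / dv) + 2;
    k1tab.assign(nk, 0.0);
    for (int i = 0; i < nk; ++i) {
      const double x = xmin + i * dv;   // V - E_K
      const double Ak1 = 0.1 / (1.0 + std::exp(0.06 * (x - 200.0)));
      const double Bk1 = (3.0 * std::exp(0.0002 * (x + 100.0)) +
                          std::exp(0.1 * (x - 10.0))) /
                         (1.0 + std::exp(-0.5 * x));
      k1tab[i] = Ak1 / (Ak1 + Bk1);
    }
  }
};

// tissue step using the tables; behaviour as tp06_step_inplace with the
// run's fixed dt baked into the gate factors
inline double tp06_step_lut(double* y, const Tp06Params& P, const Tp06Tables& T,
                            double i_sac, double i_stim, double dt,
                            double dvdt_extra) {
  const double V = y[TP_V];
  double vq = V;
  if (vq < T.vmin) vq = T.vmin;
  if (vq > T.vmax - T.dv) vq = T.vmax - T.dv;
  const double u = (vq - T.vmin) * T.inv_dv;
  const int i0 = (int)u;
  const double w = u - i0;
  const double* r0 = &T.tab[(size_t)i0 * TP06_LUT_NCOL];
  const double* r1 = r0 + TP06_LUT_NCOL;
  double row[TP06_LUT_NCOL];
  for (int cidx = 0; cidx < TP06_LUT_NCOL; ++cidx)
    row[cidx] = r0[cidx] + w * (r1[cidx] - r0[cidx]);

  const double Nai = y[TP_NAI], Ki = y[TP_KI], Cai = y[TP_CAI], CaSS = y[TP_CASS];
  const double Ek  = P.RTONF * std::log(P.Ko / Ki);
  const double Ena = P.RTONF * std::log(P.Nao / Nai);
  const double Eks = P.RTONF * std::log((P.Ko + P.pKNa * P.Nao) / (Ki + P.pKNa * Nai));
  const double Eca = 0.5 * P.RTONF * std::log(P.Cao / Cai);

  double x = V - Ek;
  if (x < T.xmin) x = T.xmin;
  if (x > T.xmax - T.dv) x = T.xmax - T.dv;
  const double uk = (x - T.xmin) * T.inv_dv;
  const int k0 = (int)uk;
  const double wk = uk - k0;
  const double rec_iK1 = T.k1tab[k0] + wk * (T.k1tab[k0 + 1] - T.k1tab[k0]);

  Tp06Currents c;
  c.INa = P.Gna * y[TP_M] * y[TP_M] * y[TP_M] * y[TP_H] * y[TP_J] * (V - Ena);
  c.ICaL = P.GCaL * y[TP_D] * y[TP_F] * y[TP_F2] * y[TP_FCASS] *
           (row[26] * CaSS - row[27] * P.Cao);
  c.Ito = P.Gto * y[TP_R] * y[TP_S] * (V - Ek);
  c.IKr = P.GKr * std::sqrt(P.Ko / 5.4) * y[TP_XR1] * y[TP_XR2] * (V - Ek);
  c.IKs = P.GKs * y[TP_XS] * y[TP_XS] * (V - Eks);
  c.IK1 = P.GK1 * rec_iK1 * (V - Ek);
  c.INaCa = row[28] * Nai * Nai * Nai - row[29] * Cai;
  c.INaK = P.knak * (P.Ko / (P.Ko + P.KmK)) * (Nai / (Nai + P.KmNa)) * row[24];
  c.IpCa = P.GpCa * Cai / (P.KpCa + Cai);
  c.IpK  = P.GpK * row[25] * (V - Ek);
  c.IbNa = P.GbNa * (V - Ena);
  c.IbCa = P.GbCa * (V - Eca);
  const double Itot = c.INa + c.ICaL + c.Ito + c.IKr + c.IKs + c.IK1 + c.INaK +
                      c.INaCa + c.IpCa + c.IpK + c.IbCa + c.IbNa + i_sac + i_stim;

  // calcium subsystem (identical to the analytic path)
  {
    double CaSR = y[TP_CASR], RR = y[TP_RBAR];
    const double kCaSR = P.maxsr - (P.maxsr - P.minsr) /
                         (1.0 + (P.EC / CaSR) * (P.EC / CaSR));
    const double k1 = P.k1p / kCaSR;
    const double k2 = P.k2p * kCaSR;
    y[TP_RBAR] = RR + dt * (P.k4 * (1.0 - RR) - k2 * CaSS * RR);
    const double OO = k1 * CaSS * CaSS * y[TP_RBAR] / (P.k3 + k1 * CaSS * CaSS);
    const double Irel = P.Vrel * OO * (CaSR - CaSS);
    const double Ileak = P.Vleak * (CaSR - Cai);
    const double Iup = P.Vmaxup / (1.0 + (P.Kup * P.Kup) / (Cai * Cai));
    const double Ixfer = P.Vxfer * (CaSS - Cai);
    const double CaCSQN = P.Bufsr * CaSR / (CaSR + P.Kbufsr);
    const double dCaSR = dt * (Iup - Irel - Ileak);
    const double bjsr = P.Bufsr - CaCSQN - dCaSR - CaSR + P.Kbufsr;
    const double cjsr = P.Kbufsr * (CaCSQN + dCaSR + CaSR);
    y[TP_CASR] = (std::sqrt(bjsr * bjsr + 4.0 * cjsr) - bjsr) / 2.0;
    const double CaSSBuf = P.Bufss * CaSS / (CaSS + P.Kbufss);
    const double dCaSS = dt * (-Ixfer * (P.Vc / P.Vss) + Irel * (P.Vsr / P.Vss) +
                               (-c.ICaL * P.invVssF2 * P.Cm));
    const double bcss = P.Bufss - CaSSBuf - dCaSS - CaSS + P.Kbufss;
    const double ccss = P.Kbufss * (CaSSBuf + dCaSS + CaSS);
    y[TP_CASS] = (std::sqrt(bcss * bcss + 4.0 * ccss) - bcss) / 2.0;
    const double CaBuf = P.Bufc * Cai / (Cai + P.Kbufc);
    const double dCai = dt * ((-(c.IbCa + c.IpCa - 2.0 * c.INaCa) * P.invVcF2 * P.Cm) -
                              (Iup - Ileak) * (P.Vsr / P.Vc) + Ixfer);
    const double bc = P.Bufc - CaBuf - dCai - Cai + P.Kbufc;
    const double cc = P.Kbufc * (CaBuf + dCai + Cai);
    y[TP_CAI] = (std::sqrt(bc * bc + 4.0 * cc) - bc) / 2.0;
  }
  y[TP_NAI] += dt * (-(c.INa + c.IbNa + 3.0 * c.INaK + 3.0 * c.INaCa) * P.invVcF * P.Cm);
  y[TP_KI]  += dt * (-(i_stim + c.IK1 + c.Ito + c.IKr + c.IKs - 2.0 * c.INaK + c.IpK) *
                     P.invVcF * P.Cm);

  // gates: voltage-dependent from the table, fCass from its own law
  static const int gidx[11] = {TP_M, TP_H, TP_J, TP_D, TP_F, TP_F2,
                               TP_R, TP_S, TP_XR1, TP_XR2, TP_XS};
  if (P.rush_larsen) {
    for (int g = 0; g < 11; ++g)
      y[gidx[g]] = row[g] - (row[g] - y[gidx[g]]) * row[12 + g];
    const double c2 = (CaSS / 0.05) * (CaSS / 0.05);
    const double finf = 0.6 / (1.0 + c2) + 0.4;
    const double ftau = 80.0 / (1.0 + c2) + 2.0;
    y[TP_FCASS] = finf - (finf - y[TP_FCASS]) * std::exp(-dt / ftau);
  } else {
    for (int g = 0; g < 11; ++g)
      y[gidx[g]] += (row[g] - y[gidx[g]]) * row[12 + g];
    const double c2 = (CaSS / 0.05) * (CaSS / 0.05);
    const double finf = 0.6 / (1.0 + c2) + 0.4;
    const double ftau = 80.0 / (1.0 + c2) + 2.0;
    y[TP_FCASS] += dt * (finf - y[TP_FCASS]) / ftau;
  }
  y[TP_V] = V + dt * (dvdt_extra - Itot);
  return Itot;
}

#endif
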