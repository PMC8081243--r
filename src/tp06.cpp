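// ten Tusscher-Panfilov 2006 human ventricular cardiomyocyte model
// (epicardial and endocardial variants), vectorized over mesh nodes.
//
// Units: mV, ms, mM; currents in pA/pF. Gates advance by Rush-Larsen
// exponential updates, voltage and concentrations by forward Euler;
// the Ca buffering updates use the analytic quadratic form so that
// concentrations stay positive.
//
// Stimulus convention: `istim` > 0 depolarizes (it enters the voltage
// equation as +istim and the K+ balance with the matching sign).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace tp06 {

const double Rgas = 8314.472, Frd = 96485.3415, Temp = 310.0;
const double RTONF = Rgas * Temp / Frd;
const double Ko = 5.4, Cao = 2.0, Nao = 140.0;
const double Vc = 0.016404, Vsr = 0.001094, Vss = 0.00005468;
const double Bufc = 0.2, Kbufc = 0.001;
const double Bufsr = 10.0, Kbufsr = 0.3;
const double Bufss = 0.4, Kbufss = 0.00025;
const double Vmaxup = 0.006375, Kup = 0.00025;
const double Vrel = 0.102, k1p = 0.15, k2p = 0.045, k3 = 0.060, k4 = 0.005;
const double EC = 1.5, maxsr = 2.5, minsr = 1.0;
const double Vleak = 0.00036, Vxfer = 0.0038;
const double CAP = 0.185;          // cell capacitance used in the flux scalings
const double Gkr = 0.153, Gk1 = 5.405, GNa = 14.838;
const double GbNa = 0.00029, GbCa = 0.000592;
const double KmK = 1.0, KmNa = 40.0, knak = 2.724;
const double GCaL = 0.00003980;
const double knaca = 1000.0, KmNai = 87.5, KmCa = 1.38, ksat = 0.1, ncag = 0.35;
const double GpCa = 0.1238, KpCa = 0.0005, GpK = 0.0146;
const double pKNa = 0.03;
const double GKS_EPI = 0.392, GKS_ENDO = 0.392;
const double GTO_EPI = 0.294, GTO_ENDO = 0.073;

const int NSTATE = 19;
// state indices
enum { iV = 0, iM, iH, iJ, iXr1, iXr2, iXs, iR, iS, iD, iF, iF2, iFcass,
       iRR, iCai, iCaSR, iCaSS, iNai, iKi };

inline void step_node(double *s, bool epi, double gks, double dt, double istim) {
  double V = s[iV];
  double Cai = s[iCai], CaSR = s[iCaSR], CaSS = s[iCaSS];
  double Nai = s[iNai], Ki = s[iKi];

  const double Ek = RTONF * std::log(Ko / Ki);
  const double Ena = RTONF * std::log(Nao / Nai);
  const double Eks = RTONF * std::log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
  const double Eca = 0.5 * RTONF * std::log(Cao / Cai);

  const double Ak1 = 0.1 / (1.0 + std::exp(0.06 * (V - Ek - 200.0)));
  const double Bk1 = (3.0 * std::exp(0.0002 * (V - Ek + 100.0)) +
                      std::exp(0.1 * (V - Ek - 10.0))) /
                     (1.0 + std::exp(-0.5 * (V - Ek)));
  const double IK1 = Gk1 * Ak1 / (Ak1 + Bk1) * (V - Ek);

  const double gto = epi ? GTO_EPI : GTO_ENDO;
  const double Ito = gto * s[iR] * s[iS] * (V - Ek);
  const double IKr = Gkr * std::sqrt(Ko / 5.4) * s[iXr1] * s[iXr2] * (V - Ek);
  const double IKs = gks * s[iXs] * s[iXs] * (V - Eks);
  const double INa = GNa * s[iM] * s[iM] * s[iM] * s[iH] * s[iJ] * (V - Ena);

  double vf = (V - 15.0) * Frd / (Rgas * Temp);
  double ICaL;
  if (std::fabs(vf) < 1e-8) {
    // limit of the GHK-type driving term at V = 15 mV
    ICaL = GCaL * s[iD] * s[iF] * s[iF2] * s[iFcass] * 2.0 * Frd *
           (0.25 * CaSS - Cao);
  } else {
    ICaL = GCaL * s[iD] * s[iF] * s[iF2] * s[iFcass] * 4.0 * (V - 15.0) *
           (Frd * Frd / (Rgas * Temp)) *
           (0.25 * CaSS * std::exp(2.0 * vf) - Cao) / (std::exp(2.0 * vf) - 1.0);
  }

  const double vfrt = V * Frd / (Rgas * Temp);
  const double INaCa =
      knaca * (1.0 / (KmNai * KmNai * KmNai + Nao * Nao * Nao)) *
      (1.0 / (KmCa + Cao)) *
      (1.0 / (1.0 + ksat * std::exp((ncag - 1.0) * vfrt))) *
      (std::exp(ncag * vfrt) * Nai * Nai * Nai * Cao -
       std::exp((ncag - 1.0) * vfrt) * Nao * Nao * Nao * Cai * 2.5);
  const double INaK = knak * (Ko / (Ko + KmK)) * (Nai / (Nai + KmNa)) /
                      (1.0 + 0.1245 * std::exp(-0.1 * vfrt) +
                       0.0353 * std::exp(-vfrt));
  const double IpCa = GpCa * Cai / (KpCa + Cai);
  const double IpK = GpK * (V - Ek) / (1.0 + std::exp((25.0 - V) / 5.98));
  const double IbNa = GbNa * (V - Ena);
  const double IbCa = GbCa * (V - Eca);

  const double Iion = IKr + IKs + IK1 + Ito + INa + IbNa + ICaL + IbCa +
                      INaK + INaCa + IpCa + IpK;

  // --- SR calcium handling ---
  const double kCaSR = maxsr - (maxsr - minsr) / (1.0 + (EC / CaSR) * (EC / CaSR));
  const double k1 = k1p / kCaSR;
  const double k2 = k2p * kCaSR;
  double RR = s[iRR];
  RR += dt * (k4 * (1.0 - RR) - k2 * CaSS * RR);
  const double OO = k1 * CaSS * CaSS * RR / (k3 + k1 * CaSS * CaSS);
  const double Irel = Vrel * OO * (CaSR - CaSS);
  const double Ileak = Vleak * (CaSR - Cai);
  const double Iup = Vmaxup / (1.0 + (Kup * Kup) / (Cai * Cai));
  const double Ixfer = Vxfer * (CaSS - Cai);

  const double CaCSQN = Bufsr * CaSR / (CaSR + Kbufsr);
  const double dCaSR = dt * (Iup - Irel - Ileak);
  const double bjsr = Bufsr - CaCSQN - dCaSR - CaSR + Kbufsr;
  const double cjsr = Kbufsr * (CaCSQN + dCaSR + CaSR);
  CaSR = (std::sqrt(bjsr * bjsr + 4.0 * cjsr) - bjsr) / 2.0;

  const double CaSSBuf = Bufss * CaSS / (CaSS + Kbufss);
  const double dCaSS = dt * (-Ixfer * (Vc / Vss) + Irel * (Vsr / Vss) +
                             (-ICaL * CAP / (2.0 * Vss * Frd)));
  const double bcss = Bufss - CaSSBuf - dCaSS - CaSS + Kbufss;
  const double ccss = Kbufss * (CaSSBuf + dCaSS + CaSS);
  CaSS = (std::sqrt(bcss * bcss + 4.0 * ccss) - bcss) / 2.0;

  const double CaBuf = Bufc * Cai / (Cai + Kbufc);
  const double dCai = dt * (-(IbCa + IpCa - 2.0 * INaCa) * CAP / (2.0 * Vc * Frd) -
                            (Iup - Ileak) * (Vsr / Vc) + Ixfer);
  const double bc = Bufc - CaBuf - dCai - Cai + Kbufc;
  const double cc = Kbufc * (CaBuf + dCai + Cai);
  Cai = (std::sqrt(bc * bc + 4.0 * cc) - bc) / 2.0;

  Nai += dt * (-(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * CAP / (Vc * Frd));
  Ki += dt * (-(-istim + IK1 + Ito + IKr + IKs - 2.0 * INaK + IpK) * CAP / (Vc * Frd));

  // --- gate rates (Rush-Larsen) ---
  const double M_INF = 1.0 / std::pow(1.0 + std::exp((-56.86 - V) / 9.03), 2.0);
  const double AM = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
  const double BM = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
                    0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
  const double TAU_M = AM * BM;
  const double H_INF = 1.0 / std::pow(1.0 + std::exp((V + 71.55) / 7.43), 2.0);
  double AH, BH, AJ, BJ;
  if (V >= -40.0) {
    AH = 0.0;
    BH = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    AJ = 0.0;
    BJ = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    AH = 0.057 * std::exp(-(V + 80.0) / 6.8);
    BH = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
    AJ = (-2.5428e4 * std::exp(0.2444 * V) - 6.948e-6 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    BJ = 0.02424 * std::exp(-0.01052 * V) /
         (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  const double TAU_H = 1.0 / (AH + BH);
  const double TAU_J = 1.0 / (AJ + BJ);
  const double J_INF = H_INF;

  const double Xr1_INF = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
  const double axr1 = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
  const double bxr1 = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
  const double TAU_Xr1 = axr1 * bxr1;
  const double Xr2_INF = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
  const double axr2 = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
  const double bxr2 = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
  const double TAU_Xr2 = axr2 * bxr2;
  const double Xs_INF = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
  const double Axs = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0));
  const double Bxs = 1.0 / (1.0 + std::exp((V - 35.0) / 15.0));
  const double TAU_Xs = Axs * Bxs + 80.0;

  const double R_INF = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
  const double TAU_R = 9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
  double S_INF, TAU_S;
  if (epi) {
    S_INF = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
    TAU_S = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
            5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
  } else {
    S_INF = 1.0 / (1.0 + std::exp((V + 28.0) / 5.0));
    TAU_S = 1000.0 * std::exp(-(V + 67.0) * (V + 67.0) / 1000.0) + 8.0;
  }

  const double D_INF = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
  const double Ad = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
  const double Bd = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
  const double Cd = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
  const double TAU_D = Ad * Bd + Cd;
  const double F_INF = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
  const double TAU_F = 1102.5 * std::exp(-(V + 27.0) * (V + 27.0) / 225.0) +
                       200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
                       180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0;
  const double F2_INF = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
  const double TAU_F2 = 562.0 * std::exp(-(V + 27.0) * (V + 27.0) / 240.0) +
                        31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
                        80.0 / (1.0 + std::exp((V + 30.0) / 10.0));
  const double FCaSS_INF = 0.6 / (1.0 + (CaSS / 0.05) * (CaSS / 0.05)) + 0.4;
  const double TAU_FCaSS = 80.0 / (1.0 + (CaSS / 0.05) * (CaSS / 0.05)) + 2.0;

  s[iM]  = M_INF - (M_INF - s[iM]) * std::exp(-dt / TAU_M);
  s[iH]  = H_INF - (H_INF - s[iH]) * std::exp(-dt / TAU_H);
  s[iJ]  = J_INF - (J_INF - s[iJ]) * std::exp(-dt / TAU_J);
  s[iXr1] = Xr1_INF - (Xr1_INF - s[iXr1]) * std::exp(-dt / TAU_Xr1);
  s[iXr2] = Xr2_INF - (Xr2_INF - s[iXr2]) * std::exp(-dt / TAU_Xr2);
  s[iXs] = Xs_INF - (Xs_INF - s[iXs]) * std::exp(-dt / TAU_Xs);
  s[iR]  = R_INF - (R_INF - s[iR]) * std::exp(-dt / TAU_R);
  s[iS]  = S_INF - (S_INF - s[iS]) * std::exp(-dt / TAU_S);
  s[iD]  = D_INF - (D_INF - s[iD]) * std::exp(-dt / TAU_D);
  s[iF]  = F_INF - (F_INF - s[iF]) * std::exp(-dt / TAU_F);
  s[iF2] = F2_INF - (F2_INF - s[iF2]) * std::exp(-dt / TAU_F2);
  s[iFcass] = FCaSS_INF - (FCaSS_INF - s[iFcass]) * std::exp(-dt / TAU_FCaSS);

  s[iV] = V + dt * (-Iion + istim);
  s[iRR] = RR;
  s[iCai] = Cai;
  s[iCaSR] = CaSR;
  s[iCaSS] = CaSS;
  s[iNai] = Nai;
  s[iKi] = Ki;
}

} // namespace tp06

// Initial state published with the model (pre-settling values).
// [[Rcpp::export]]
NumericVector tp06_init_state_cpp() {
  NumericVector s(tp06::NSTATE);
  s[tp06::iV] = -86.2;
  s[tp06::iM] = 0.0;     s[tp06::iH] = 0.75;  s[tp06::iJ] = 0.75;
  s[tp06::iXr1] = 0.0;   s[tp06::iXr2] = 1.0; s[tp06::iXs] = 0.0;
  s[tp06::iR] = 0.0;     s[tp06::iS] = 1.0;
  s[tp06::iD] = 0.0;     s[tp06::iF] = 1.0;   s[tp06::iF2] = 1.0;
  s[tp06::iFcass] = 1.0; s[tp06::iRR] = 1.0;
  s[tp06::iCai] = 0.00007; s[tp06::iCaSR] = 1.3; s[tp06::iCaSS] = 0.00007;
  s[tp06::iNai] = 7.67;  s[tp06::iKi] = 138.3;
  return s;
}

// Advance a population of cells in place over nsub substeps of length dt.
// state: n x 19 matrix; epi: int (0/1) per node; gks per node; istim pA/pF
// per node (depolarizing positive, applied for the whole call).
// [[Rcpp::export]]
void tp06_advance_cpp(NumericMatrix state, IntegerVector epi,
                      NumericVector gks, double dt, int nsub,
                      NumericVector istim) {
  const int n = state.nrow();
  if (state.ncol() != tp06::NSTATE) stop("state must have 19 columns");
  std::vector<double> buf(tp06::NSTATE);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < tp06::NSTATE; ++k) buf[k] = state(i, k);
    const bool e = epi[i] != 0;
    const double g = gks[i], is = istim[i];
    for (int m = 0; m < nsub; ++m) tp06::step_node(buf.data(), e, g, dt, is);
    for (int k = 0; k < tp06::NSTATE; ++k) state(i, k) = buf[k];
    if (!std::isfinite(buf[tp06::iV]))
      stop("non-finite membrane voltage at node %d", i + 1);
  }
}

// Single-cell run: paced train of rectangular stimuli; returns V sampled
// every `sample_dt` ms plus the final state.
// [[Rcpp::export]]
List tp06_single_cpp(bool epi, double gks, double dt, double duration,
                     NumericVector stim_onset, double stim_dur,
                     double stim_amp, double sample_dt,
                     NumericVector state0) {
  std::vector<double> s(tp06::NSTATE);
  for (int k = 0; k < tp06::NSTATE; ++k) s[k] = state0[k];
  const int nstep = (int)std::llround(duration / dt);
  const int every = std::max(1, (int)std::llround(sample_dt / dt));
  std::vector<double> tout, vout;
  tout.reserve(nstep / every + 2);
  vout.reserve(nstep / every + 2);
  tout.push_back(0.0);
  vout.push_back(s[tp06::iV]);
  for (int m = 1; m <= nstep; ++m) {
    const double t = (m - 1) * dt;
    double is = 0.0;
    for (int q = 0; q < stim_onset.size(); ++q)
      if (t >= stim_onset[q] && t < stim_onset[q] + stim_dur) { is = stim_amp; break; }
    tp06::step_node(s.data(), epi, gks, dt, is);
    if (!std::isfinite(s[tp06::iV])) stop("non-finite membrane voltage");
    if (m % every == 0) {
      tout.push_back(m * dt);
      vout.push_back(s[tp06::iV]);
    }
  }
  return List::create(_["t"] = tout, _["V"] = vout,
                      _["state"] = NumericVector(s.begin(), s.end()));
}

// Two-variable excitable test cell (Aliev-Panfilov kinetics rescaled to mV),
// exposed behind the same advance interface for fast PDE solver tests.
// state columns: V (mV), w (recovery).
// [[Rcpp::export]]
void fhn_advance_cpp(NumericMatrix state, double dt, int nsub,
                     NumericVector istim) {
  const int n = state.nrow();
  const double k = 8.0, a = 0.15, eps0 = 0.002, mu1 = 0.2, mu2 = 0.3;
  const double Vr = -85.0, Vamp = 100.0, tsc = 12.9; // ms per model time unit
  for (int i = 0; i < n; ++i) {
    double V = state(i, 0), w = state(i, 1);
    for (int m = 0; m < nsub; ++m) {
      const double u = (V - Vr) / Vamp;
      const double eps = eps0 + mu1 * w / (u + mu2);
      const double du = -(k * u * (u - a) * (u - 1.0)) - u * w;
      const double dw = eps * (-w - k * u * (u - a - 1.0));
      V += dt * (du * Vamp / tsc + istim[i]);
      w += dt * dw / tsc;
    }
    state(i, 0) = V;
    state(i, 1) = w;
  }
}
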