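// ten Tusscher-Panfilov (2006) human ventricular myocyte model (epicardial
// variant) with ischemic modifications (INa/ICaL scaling, elevated [K+]o,
// ATP-sensitive K+ current), plus an operator-split monodomain stepper on
// structured 2D grids. Gates advance by Rush-Larsen, concentrations by
// forward Euler with analytic-buffer updates, diffusion by explicit finite
// differences with no-flux boundaries.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// physical constants
static const double Rgas = 8314.472;   // mJ/(mol K)
static const double Temp = 310.0;      // K
static const double Frdy = 96485.3415; // C/mol
static const double RTONF = Rgas * Temp / Frdy; // mV

// fixed TP06 parameters (epicardial)
static const double Cm = 0.185;
static const double Vc = 0.016404, Vsr = 0.001094, Vss = 0.00005468;
static const double Bufc = 0.2, Kbufc = 0.001;
static const double Bufsr = 10.0, Kbufsr = 0.3;
static const double Bufss = 0.4, Kbufss = 0.00025;
static const double Vmaxup = 0.006375, Kup = 0.00025;
static const double Vrel = 0.102, k1p = 0.15, k2p = 0.045, k3 = 0.060,
                    k4 = 0.005, EC = 1.5, maxsr = 2.5, minsr = 1.0;
static const double Vleak = 0.00036, Vxfer = 0.0038;
static const double Nao = 140.0, Cao = 2.0;
static const double GNa = 14.838, GK1 = 5.405, Gto_epi = 0.294;
static const double GCaL = 0.0000398;
static const double GbNa = 0.00029, GbCa = 0.000592;
static const double KpCa = 0.0005;
static const double knak = 2.724, KmK = 1.0, KmNa = 40.0;
static const double knaca = 1000.0, Ksat = 0.1, n_gamma = 0.35;
static const double KmNai = 87.5, KmCa = 1.38, alpha_naca = 2.5;
static const double pKNa = 0.03;

// state layout (NSTATE doubles per cell)
#define NSTATE 19
// 0 V, 1 Ki, 2 Nai, 3 Cai, 4 CaSS, 5 CaSR, 6 m, 7 h, 8 j,
// 9 xr1, 10 xr2, 11 xs, 12 r, 13 s, 14 d, 15 f, 16 f2, 17 fcass, 18 Rq

// tunable parameter layout (per region row)
#define NPAR 10
// 0 Ko, 1 ina_scale, 2 ical_scale, 3 fatp, 4 gkatp,
// 5 GKr, 6 GKs, 7 GpCa, 8 GpK, 9 tauf_mult

struct Gate { double inf, tau; };

struct Rates {
  Gate m, h, j, xr1, xr2, xs, r, s, d, f, f2, fcass;
  double Itot;   // total ionic current (pA/pF), excludes stimulus
  double dNai, dKi_ion;        // dKi_ion excludes stimulus term
  double Irel, Ileak, Iup, Ixfer, dRq;
  double ICaL, INaCa, IbCa, IpCa;
};

// compute all currents and gate kinetics for one cell
static void tp06_rates(const double* s, const double* p, Rates& rt) {
  const double V = s[0], Ki = s[1], Nai = s[2], Cai = s[3], CaSS = s[4],
               CaSR = s[5];
  const double Ko = p[0];

  const double EK = RTONF * std::log(Ko / Ki);
  const double ENa = RTONF * std::log(Nao / Nai);
  const double EKs = RTONF * std::log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
  const double ECa = 0.5 * RTONF * std::log(Cao / Cai);

  // fast Na+
  rt.m.inf = 1.0 / std::pow(1.0 + std::exp((-56.86 - V) / 9.03), 2.0);
  {
    double am = 1.0 / (1.0 + std::exp((-60.0 - V) / 5.0));
    double bm = 0.1 / (1.0 + std::exp((V + 35.0) / 5.0)) +
                0.1 / (1.0 + std::exp((V - 50.0) / 200.0));
    rt.m.tau = am * bm;
  }
  rt.h.inf = 1.0 / std::pow(1.0 + std::exp((V + 71.55) / 7.43), 2.0);
  {
    double ah, bh;
    if (V >= -40.0) {
      ah = 0.0;
      bh = 0.77 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    } else {
      ah = 0.057 * std::exp(-(V + 80.0) / 6.8);
      bh = 2.7 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.3485 * V);
    }
    rt.h.tau = 1.0 / (ah + bh);
  }
  rt.j.inf = rt.h.inf;
  {
    double aj, bj;
    if (V >= -40.0) {
      aj = 0.0;
      bj = 0.6 * std::exp(0.057 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
    } else {
      aj = (-2.5428e4 * std::exp(0.2444 * V) -
            6.948e-6 * std::exp(-0.04391 * V)) *
           (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
      bj = 0.02424 * std::exp(-0.01052 * V) /
           (1.0 + std::exp(-0.1378 * (V + 40.14)));
    }
    rt.j.tau = 1.0 / (aj + bj);
  }
  const double INa =
      p[1] * GNa * s[6] * s[6] * s[6] * s[7] * s[8] * (V - ENa);

  // L-type Ca2+
  rt.d.inf = 1.0 / (1.0 + std::exp((-8.0 - V) / 7.5));
  {
    double ad = 1.4 / (1.0 + std::exp((-35.0 - V) / 13.0)) + 0.25;
    double bd = 1.4 / (1.0 + std::exp((V + 5.0) / 5.0));
    double cd = 1.0 / (1.0 + std::exp((50.0 - V) / 20.0));
    rt.d.tau = ad * bd + cd;
  }
  rt.f.inf = 1.0 / (1.0 + std::exp((V + 20.0) / 7.0));
  rt.f.tau = p[9] * (1102.5 * std::exp(-(V + 27.0) * (V + 27.0) / 225.0) +
                     200.0 / (1.0 + std::exp((13.0 - V) / 10.0)) +
                     180.0 / (1.0 + std::exp((V + 30.0) / 10.0)) + 20.0);
  rt.f2.inf = 0.67 / (1.0 + std::exp((V + 35.0) / 7.0)) + 0.33;
  rt.f2.tau = 562.0 * std::exp(-(V + 27.0) * (V + 27.0) / 240.0) +
              31.0 / (1.0 + std::exp((25.0 - V) / 10.0)) +
              80.0 / (1.0 + std::exp((V + 30.0) / 10.0));
  {
    double c2 = (CaSS / 0.05) * (CaSS / 0.05);
    rt.fcass.inf = 0.6 / (1.0 + c2) + 0.4;
    rt.fcass.tau = 80.0 / (1.0 + c2) + 2.0;
  }
  double ICaL;
  {
    double vf = 2.0 * (V - 15.0) / RTONF; // 2(V-15)F/RT
    if (std::fabs(vf) < 1e-7) vf = (vf >= 0) ? 1e-7 : -1e-7; // V = 15 mV
    double num = 0.25 * CaSS * std::exp(vf) - Cao;
    double den = std::exp(vf) - 1.0;
    ICaL = p[2] * GCaL * s[14] * s[15] * s[16] * s[17] * 2.0 * vf * Frdy *
           (num / den);
  }

  // transient outward
  rt.r.inf = 1.0 / (1.0 + std::exp((20.0 - V) / 6.0));
  rt.r.tau = 9.5 * std::exp(-(V + 40.0) * (V + 40.0) / 1800.0) + 0.8;
  rt.s.inf = 1.0 / (1.0 + std::exp((V + 20.0) / 5.0));
  rt.s.tau = 85.0 * std::exp(-(V + 45.0) * (V + 45.0) / 320.0) +
             5.0 / (1.0 + std::exp((V - 20.0) / 5.0)) + 3.0;
  const double Ito = Gto_epi * s[12] * s[13] * (V - EK);

  // rapid delayed rectifier
  rt.xr1.inf = 1.0 / (1.0 + std::exp((-26.0 - V) / 7.0));
  {
    double a = 450.0 / (1.0 + std::exp((-45.0 - V) / 10.0));
    double b = 6.0 / (1.0 + std::exp((V + 30.0) / 11.5));
    rt.xr1.tau = a * b;
  }
  rt.xr2.inf = 1.0 / (1.0 + std::exp((V + 88.0) / 24.0));
  {
    double a = 3.0 / (1.0 + std::exp((-60.0 - V) / 20.0));
    double b = 1.12 / (1.0 + std::exp((V - 60.0) / 20.0));
    rt.xr2.tau = a * b;
  }
  const double IKr =
      p[5] * std::sqrt(Ko / 5.4) * s[9] * s[10] * (V - EK);

  // slow delayed rectifier
  rt.xs.inf = 1.0 / (1.0 + std::exp((-5.0 - V) / 14.0));
  {
    double a = 1400.0 / std::sqrt(1.0 + std::exp((5.0 - V) / 6.0));
    double b = 1.0 / (1.0 + std::exp((V - 35.0) / 15.0));
    rt.xs.tau = a * b + 80.0;
  }
  const double IKs = p[6] * s[11] * s[11] * (V - EKs);

  // inward rectifier
  double IK1;
  {
    double a = 0.1 / (1.0 + std::exp(0.06 * (V - EK - 200.0)));
    double b = (3.0 * std::exp(0.0002 * (V - EK + 100.0)) +
                std::exp(0.1 * (V - EK - 10.0))) /
               (1.0 + std::exp(-0.5 * (V - EK)));
    IK1 = GK1 * std::sqrt(Ko / 5.4) * (a / (a + b)) * (V - EK);
  }

  // pumps, exchangers, background
  const double INaK = knak * (Ko / (Ko + KmK)) * (Nai / (Nai + KmNa)) /
                      (1.0 + 0.1245 * std::exp(-0.1 * V / RTONF) +
                       0.0353 * std::exp(-V / RTONF));
  const double INaCa =
      knaca *
      (std::exp(n_gamma * V / RTONF) * Nai * Nai * Nai * Cao -
       std::exp((n_gamma - 1.0) * V / RTONF) * Nao * Nao * Nao * Cai *
           alpha_naca) /
      ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
       (1.0 + Ksat * std::exp((n_gamma - 1.0) * V / RTONF)));
  const double IpCa = p[7] * Cai / (Cai + KpCa);
  const double IpK = p[8] * (V - EK) / (1.0 + std::exp((25.0 - V) / 5.98));
  const double IbNa = GbNa * (V - ENa);
  const double IbCa = GbCa * (V - ECa);

  // ATP-sensitive K+ current (Ferrero-type)
  const double IKatp =
      p[4] * p[3] * std::pow(Ko / 5.4, 0.24) * (V - EK);

  rt.Itot = INa + ICaL + Ito + IKr + IKs + IK1 + INaK + INaCa + IpCa + IpK +
            IbNa + IbCa + IKatp;
  rt.ICaL = ICaL;
  rt.INaCa = INaCa;
  rt.IbCa = IbCa;
  rt.IpCa = IpCa;

  // SR calcium handling
  {
    double kCaSR =
        maxsr - (maxsr - minsr) / (1.0 + (EC / CaSR) * (EC / CaSR));
    double k1 = k1p / kCaSR;
    double k2 = k2p * kCaSR;
    rt.dRq = k4 * (1.0 - s[18]) - k2 * CaSS * s[18];
    double O = k1 * CaSS * CaSS * s[18] / (k3 + k1 * CaSS * CaSS);
    rt.Irel = Vrel * O * (CaSR - CaSS);
  }
  rt.Ileak = Vleak * (CaSR - Cai);
  rt.Iup = Vmaxup / (1.0 + (Kup / Cai) * (Kup / Cai));
  rt.Ixfer = Vxfer * (CaSS - Cai);

  rt.dNai = -(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) / (Vc * Frdy) * Cm;
  rt.dKi_ion =
      -(IK1 + Ito + IKr + IKs + IKatp - 2.0 * INaK + IpK) / (Vc * Frdy) * Cm;
}

static inline double rl_update(double x, const Gate& g, double dt) {
  return g.inf + (x - g.inf) * std::exp(-dt / g.tau);
}

static inline double clamp01(double x) {
  return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x);
}

// advance one cell by dt; Istim in pA/pF (negative = depolarizing)
static void tp06_step(double* s, const double* p, double Istim, double dt) {
  Rates rt;
  tp06_rates(s, p, rt);

  // voltage
  s[0] += -dt * (rt.Itot + Istim);

  // gates (Rush-Larsen)
  s[6] = clamp01(rl_update(s[6], rt.m, dt));
  s[7] = clamp01(rl_update(s[7], rt.h, dt));
  s[8] = clamp01(rl_update(s[8], rt.j, dt));
  s[9] = clamp01(rl_update(s[9], rt.xr1, dt));
  s[10] = clamp01(rl_update(s[10], rt.xr2, dt));
  s[11] = clamp01(rl_update(s[11], rt.xs, dt));
  s[12] = clamp01(rl_update(s[12], rt.r, dt));
  s[13] = clamp01(rl_update(s[13], rt.s, dt));
  s[14] = clamp01(rl_update(s[14], rt.d, dt));
  s[15] = clamp01(rl_update(s[15], rt.f, dt));
  s[16] = clamp01(rl_update(s[16], rt.f2, dt));
  s[17] = clamp01(rl_update(s[17], rt.fcass, dt));
  s[18] = clamp01(s[18] + dt * rt.dRq);

  // SR Ca (analytic buffering, quadratic solve)
  {
    double CaCSQN = Bufsr * s[5] / (s[5] + Kbufsr);
    double dCaSR = dt * (rt.Iup - rt.Irel - rt.Ileak);
    double b = Bufsr - CaCSQN - dCaSR - s[5] + Kbufsr;
    double c = Kbufsr * (CaCSQN + dCaSR + s[5]);
    s[5] = (std::sqrt(b * b + 4.0 * c) - b) / 2.0;
  }
  // subspace Ca
  {
    double CaSSBuf = Bufss * s[4] / (s[4] + Kbufss);
    double dCaSS =
        dt * (-rt.Ixfer * (Vc / Vss) + rt.Irel * (Vsr / Vss) +
              (-rt.ICaL / (2.0 * Vss * Frdy) * Cm));
    double b = Bufss - CaSSBuf - dCaSS - s[4] + Kbufss;
    double c = Kbufss * (CaSSBuf + dCaSS + s[4]);
    s[4] = (std::sqrt(b * b + 4.0 * c) - b) / 2.0;
  }
  // cytosolic Ca
  {
    double CaBuf = Bufc * s[3] / (s[3] + Kbufc);
    double dCai =
        dt * ((-(rt.IbCa + rt.IpCa - 2.0 * rt.INaCa) / (2.0 * Vc * Frdy) *
               Cm) -
              (rt.Iup - rt.Ileak) * (Vsr / Vc) + rt.Ixfer);
    double b = Bufc - CaBuf - dCai - s[3] + Kbufc;
    double c = Kbufc * (CaBuf + dCai + s[3]);
    s[3] = (std::sqrt(b * b + 4.0 * c) - b) / 2.0;
  }
  // Na+, K+ (stimulus current assigned to K+, as in the published code)
  s[2] += dt * rt.dNai;
  s[1] += dt * (rt.dKi_ion - Istim / (Vc * Frdy) * Cm);
}

// [[Rcpp::export]]
NumericVector cpp_tp06_currents(NumericVector state, NumericVector params) {
  if (state.size() != NSTATE) stop("state must have %d entries", NSTATE);
  if (params.size() != NPAR) stop("params must have %d entries", NPAR);
  Rates rt;
  tp06_rates(REAL(state), REAL(params), rt);
  // recompute individual currents for reporting
  const double* s = REAL(state);
  const double* p = REAL(params);
  double V = s[0], Ki = s[1], Nai = s[2], Cai = s[3];
  double EK = RTONF * std::log(p[0] / Ki);
  double ENa = RTONF * std::log(Nao / Nai);
  double EKs = RTONF * std::log((p[0] + pKNa * Nao) / (Ki + pKNa * Nai));
  double ECa = 0.5 * RTONF * std::log(Cao / Cai);
  double INa = p[1] * GNa * s[6] * s[6] * s[6] * s[7] * s[8] * (V - ENa);
  double IKatp = p[4] * p[3] * std::pow(p[0] / 5.4, 0.24) * (V - EK);
  NumericVector out = NumericVector::create(
      _["I_total"] = rt.Itot, _["I_Na"] = INa, _["I_CaL"] = rt.ICaL,
      _["I_NaCa"] = rt.INaCa, _["I_pCa"] = rt.IpCa, _["I_bCa"] = rt.IbCa,
      _["I_Katp"] = IKatp, _["E_K"] = EK, _["E_Na"] = ENa, _["E_Ks"] = EKs,
      _["E_Ca"] = ECa);
  return out;
}

// full state time-derivative (gates as (inf-x)/tau); for oracle checks
// [[Rcpp::export]]
NumericVector cpp_tp06_derivatives(NumericVector state, NumericVector params,
                                   double istim) {
  if (state.size() != NSTATE) stop("state must have %d entries", NSTATE);
  Rates rt;
  const double* s = REAL(state);
  tp06_rates(s, REAL(params), rt);
  NumericVector d(NSTATE);
  d[0] = -(rt.Itot + istim);
  d[1] = rt.dKi_ion - istim / (Vc * Frdy) * Cm;
  d[2] = rt.dNai;
  // concentration derivatives with buffering factors omitted (raw fluxes);
  // reported for diagnostic use only
  d[3] = (-(rt.IbCa + rt.IpCa - 2.0 * rt.INaCa) / (2.0 * Vc * Frdy) * Cm) -
         (rt.Iup - rt.Ileak) * (Vsr / Vc) + rt.Ixfer;
  d[4] = -rt.Ixfer * (Vc / Vss) + rt.Irel * (Vsr / Vss) -
         rt.ICaL / (2.0 * Vss * Frdy) * Cm;
  d[5] = rt.Iup - rt.Irel - rt.Ileak;
  const Gate* gs[12] = {&rt.m, &rt.h,  &rt.j,  &rt.xr1, &rt.xr2, &rt.xs,
                        &rt.r, &rt.s,  &rt.d,  &rt.f,   &rt.f2,  &rt.fcass};
  for (int k = 0; k < 12; ++k) d[6 + k] = (gs[k]->inf - s[6 + k]) / gs[k]->tau;
  d[18] = rt.dRq;
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_tp06_initial_state() {
  NumericVector s(NSTATE);
  s[0] = -85.23;  s[1] = 136.89;  s[2] = 8.604;   s[3] = 0.000126;
  s[4] = 0.00036; s[5] = 3.64;    s[6] = 0.00172; s[7] = 0.7444;
  s[8] = 0.7045;  s[9] = 0.00621; s[10] = 0.4712; s[11] = 0.0095;
  s[12] = 2.42e-8; s[13] = 0.999998; s[14] = 3.373e-5; s[15] = 0.7888;
  s[16] = 0.9755; s[17] = 0.9953; s[18] = 0.9073;
  return s;
}

// paced single-cell run. stim_times: onsets (ms). Records V every
// record_stride steps. Returns trace + final state.
// [[Rcpp::export]]
List cpp_simulate_cell(NumericVector params, NumericVector init_state,
                       NumericVector stim_times, double stim_dur,
                       double stim_amp, double t_end, double dt,
                       int record_stride) {
  if (init_state.size() != NSTATE) stop("bad state length");
  std::vector<double> s(init_state.begin(), init_state.end());
  const double* p = REAL(params);
  long nstep = (long)std::ceil(t_end / dt);
  std::vector<double> tv, vv;
  tv.reserve(nstep / record_stride + 2);
  vv.reserve(nstep / record_stride + 2);
  int nstim = stim_times.size();
  for (long i = 0; i < nstep; ++i) {
    double t = i * dt;
    double Istim = 0.0;
    for (int k = 0; k < nstim; ++k) {
      if (t >= stim_times[k] && t < stim_times[k] + stim_dur) {
        Istim = -stim_amp;
        break;
      }
    }
    if (i % record_stride == 0) {
      tv.push_back(t);
      vv.push_back(s[0]);
    }
    tp06_step(s.data(), p, Istim, dt);
    if (!std::isfinite(s[0]) || std::fabs(s[0]) > 200.0)
      stop("numerical blow-up at step %ld (t = %.2f ms, V = %g mV)", i, t,
           s[0]);
  }
  tv.push_back(nstep * dt);
  vv.push_back(s[0]);
  return List::create(_["time"] = wrap(tv), _["V"] = wrap(vv),
                      _["final_state"] = wrap(s));
}

// ---------------------------------------------------------------------------
// monodomain stepper
//
// grid: nx x ny cells, column-major index i + nx*j. mask[cell] = 1 tissue,
// 0 void. region[cell] indexes a row of params_mat (NPAR columns).
// Diffusion tensor per cell: Dxx, Dyy, Dxy in mm^2/ms. No-flux at domain
// boundary and tissue/void interfaces (face conductance = 0).
//
// stim_cells: list of integer vectors (0-based cell ids); stim_onset,
// stim_dur, stim_amp aligned vectors.
//
// Records activation events (upward crossings of act_threshold with
// lockout) and V snapshots every vstride steps (0 = none).
// [[Rcpp::export]]
List cpp_run_monodomain(int nx, int ny, double dx, double dt, double t_end,
                        NumericMatrix params_mat, IntegerVector region,
                        IntegerVector mask, NumericVector Dxx,
                        NumericVector Dyy, NumericVector Dxy,
                        NumericMatrix init_state, List stim_cells,
                        NumericVector stim_onset, NumericVector stim_dur,
                        NumericVector stim_amp, double act_threshold,
                        double act_lockout, int vstride, int ndiff_sub,
                        double t0, bool do_reaction = true) {
  const int n = nx * ny;
  if (init_state.nrow() != n || init_state.ncol() != NSTATE)
    stop("init_state must be n_cells x %d", NSTATE);
  if (region.size() != n || mask.size() != n) stop("bad region/mask length");

  std::vector<double> S(init_state.begin(), init_state.end()); // col-major
  std::vector<double> Vbuf(n), Vnew(n);
  std::vector<double> stim_now(n, 0.0);
  std::vector<double> last_act(n, -1e9);
  std::vector<double> prevV(n);

  const int nstim = stim_onset.size();
  std::vector<std::vector<int> > scells(nstim);
  for (int k = 0; k < nstim; ++k) {
    IntegerVector v = stim_cells[k];
    scells[k].assign(v.begin(), v.end());
  }

  std::vector<int> act_cell;
  std::vector<double> act_time;
  std::vector<double> vsnap_t;
  std::vector<double> vsnap; // vstride snapshots, length n each

  const long nstep = (long)std::ceil(t_end / dt);
  const double ddt = dt / ndiff_sub;
  const double inv_dx2 = 1.0 / (dx * dx);

  for (int c = 0; c < n; ++c) prevV[c] = S[c]; // V is column 0

  for (long istep = 0; istep < nstep; ++istep) {
    double t = t0 + istep * dt;

    // stimulus field
    std::fill(stim_now.begin(), stim_now.end(), 0.0);
    for (int k = 0; k < nstim; ++k) {
      if (t >= stim_onset[k] && t < stim_onset[k] + stim_dur[k]) {
        for (size_t q = 0; q < scells[k].size(); ++q)
          stim_now[scells[k][q]] = -stim_amp[k];
      }
    }

    // reaction step per tissue cell
    double sloc[NSTATE];
    for (int c = 0; do_reaction && c < n; ++c) {
      if (!mask[c]) continue;
      for (int q = 0; q < NSTATE; ++q) sloc[q] = S[c + n * q];
      double pr[NPAR]; // NumericMatrix is column-major; copy the row
      for (int q = 0; q < NPAR; ++q) pr[q] = params_mat(region[c], q);
      tp06_step(sloc, pr, stim_now[c], dt);
      if (!std::isfinite(sloc[0]) || std::fabs(sloc[0]) > 200.0)
        stop("numerical blow-up at t = %.2f ms, cell %d (V = %g)", t, c,
             sloc[0]);
      for (int q = 0; q < NSTATE; ++q) S[c + n * q] = sloc[q];
    }

    // diffusion substeps on V
    for (int sub = 0; sub < ndiff_sub; ++sub) {
      for (int c = 0; c < n; ++c) Vbuf[c] = S[c];
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i < nx; ++i) {
          int c = i + nx * j;
          if (!mask[c]) { Vnew[c] = Vbuf[c]; continue; }
          double flux = 0.0;
          // x faces (harmonic-free simple average of face D)
          if (i + 1 < nx && mask[c + 1]) {
            double Df = 0.5 * (Dxx[c] + Dxx[c + 1]);
            flux += Df * (Vbuf[c + 1] - Vbuf[c]);
          }
          if (i > 0 && mask[c - 1]) {
            double Df = 0.5 * (Dxx[c] + Dxx[c - 1]);
            flux += Df * (Vbuf[c - 1] - Vbuf[c]);
          }
          if (j + 1 < ny && mask[c + nx]) {
            double Df = 0.5 * (Dyy[c] + Dyy[c + nx]);
            flux += Df * (Vbuf[c + nx] - Vbuf[c]);
          }
          if (j > 0 && mask[c - nx]) {
            double Df = 0.5 * (Dyy[c] + Dyy[c - nx]);
            flux += Df * (Vbuf[c - nx] - Vbuf[c]);
          }
          // cross terms, interior only
          if (Dxy[c] != 0.0 && i > 0 && i + 1 < nx && j > 0 && j + 1 < ny &&
              mask[c + 1] && mask[c - 1] && mask[c + nx] && mask[c - nx] &&
              mask[c + 1 + nx] && mask[c - 1 - nx] && mask[c + 1 - nx] &&
              mask[c - 1 + nx]) {
            double mixed = (Vbuf[c + 1 + nx] + Vbuf[c - 1 - nx] -
                            Vbuf[c + 1 - nx] - Vbuf[c - 1 + nx]) * 0.25;
            flux += 2.0 * Dxy[c] * mixed;
          }
          Vnew[c] = Vbuf[c] + ddt * inv_dx2 * flux;
        }
      }
      for (int c = 0; c < n; ++c) S[c] = Vnew[c];
    }

    // activation detection
    double tnext = t + dt;
    for (int c = 0; c < n; ++c) {
      if (!mask[c]) continue;
      double v = S[c];
      if (prevV[c] < act_threshold && v >= act_threshold &&
          tnext - last_act[c] >= act_lockout) {
        act_cell.push_back(c);
        act_time.push_back(tnext);
        last_act[c] = tnext;
      }
      prevV[c] = v;
    }

    if (vstride > 0 && (istep % vstride == 0)) {
      vsnap_t.push_back(t);
      for (int c = 0; c < n; ++c) vsnap.push_back(S[c]);
    }
  }

  NumericMatrix fin(n, NSTATE);
  std::copy(S.begin(), S.end(), fin.begin());
  List out = List::create(
      _["act_cell"] = wrap(act_cell), _["act_time"] = wrap(act_time),
      _["final_state"] = fin, _["snap_time"] = wrap(vsnap_t));
  if (vstride > 0) {
    int nsnap = vsnap_t.size();
    NumericMatrix M(n, nsnap);
    std::copy(vsnap.begin(), vsnap.end(), M.begin());
    out["V"] = M;
  }
  return out;
}
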