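// Courtemanche-Ramirez-Nattel (1998) human atrial ionic model and a fused
// explicit monodomain stepper on a regular 2D grid.
//
// Units: mV, ms, pA/pF (numerically mV/ms), mM, mm.  Cm = 100 pF.
// State layout (21 variables, order fixed across the package):
//   0 V, 1 m, 2 h, 3 j, 4 oa, 5 oi, 6 ua, 7 ui, 8 xr, 9 xs,
//   10 d, 11 f, 12 fCa, 13 u, 14 v, 15 w, 16 Nai, 17 Ki, 18 Cai,
//   19 CaUp, 20 CaRel
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstring>
using namespace Rcpp;

static const int NSTATE = 21;

// physical constants
static const double Rgas = 8.3143, Temp = 310.0, Frd = 96.4867;
static const double RTF = Rgas * Temp / Frd;          // ~26.713 mV
static const double Cm = 100.0;                       // pF
static const double Vi = 13668.0, Vup = 1109.52, Vrel = 96.48; // um^3
static const double Ko = 5.4, Nao = 140.0, Cao = 1.8; // mM
static const double gKr = 0.029411765, gKs = 0.12941176;
static const double gbCa = 0.001131, gbNa = 0.0006744375;
static const double INaKmax = 0.59933874, IpCamax = 0.275;
static const double KQ10 = 3.0, gam = 0.35;
static const double KmNai = 10.0, KmKo = 1.5, KmNa = 87.5, KmCa = 1.38, ksat = 0.1;
static const double krel = 30.0, kup = 0.00092, Caupmax = 15.0;
static const double CMDNmax = 0.05, TRPNmax = 0.07, CSQNmax = 10.0;
static const double KmCMDN = 0.00238, KmTRPN = 0.0005, KmCSQN = 0.8;
static const double tautr = 180.0, taufca = 2.0, tauu = 8.0;

struct Params {
  double gNa, gto, gCaL, gK1, sKur, INaCaMax, IupMax;
};

static Params params_from_list(const List& p) {
  Params q;
  q.gNa = as<double>(p["gNa"]);
  q.gto = as<double>(p["gto"]);
  q.gCaL = as<double>(p["gCaL"]);
  q.gK1 = as<double>(p["gK1"]);
  q.sKur = as<double>(p["sKur"]);
  q.INaCaMax = as<double>(p["INaCaMax"]);
  q.IupMax = as<double>(p["IupMax"]);
  return q;
}

static inline double safe_ratio(double num, double den, double lim) {
  return (std::fabs(den) < 1e-10) ? lim : num / den;
}

static inline double gkur_of_v(double V) {
  return 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));
}

// steady state and time constant for the 12 V-dependent gates
// order: m h j oa oi ua ui xr xs d f w
static void gate_inf_tau(double V, double* inf, double* tau) {
  // fast Na
  double x = V + 47.13;
  double am = safe_ratio(0.32 * x, 1.0 - std::exp(-0.1 * x), 3.2);
  double bm = 0.08 * std::exp(-V / 11.0);
  double ah, bh, aj, bj;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + std::exp(-(V + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  } else {
    ah = 0.135 * std::exp(-(V + 80.0) / 6.8);
    bh = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
    aj = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    bj = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  }
  inf[0] = am / (am + bm); tau[0] = 1.0 / (am + bm);
  inf[1] = ah / (ah + bh); tau[1] = 1.0 / (ah + bh);
  inf[2] = aj / (aj + bj); tau[2] = 1.0 / (aj + bj);
  // Ito gates
  double aoa = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  double boa = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  inf[3] = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
  tau[3] = 1.0 / ((aoa + boa) * KQ10);
  double aoi = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
  double boi = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
  inf[4] = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));
  tau[4] = 1.0 / ((aoi + boi) * KQ10);
  // IKur gates (ua rates share the oa form)
  inf[5] = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
  tau[5] = tau[3];
  double aui = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
  double bui = std::exp((V - 158.0) / 16.0);
  inf[6] = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));
  tau[6] = 1.0 / ((aui + bui) * KQ10);
  // IKr, IKs
  double y = V + 14.1;
  double axr = safe_ratio(0.0003 * y, 1.0 - std::exp(-y / 5.0), 0.0015);
  double z = V - 3.3328;
  double bxr = safe_ratio(7.3898e-5 * z, std::exp(z / 5.1237) - 1.0, 7.3898e-5 * 5.1237);
  inf[7] = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));
  tau[7] = 1.0 / (axr + bxr);
  double w1 = V - 19.9;
  double axs = safe_ratio(4e-5 * w1, 1.0 - std::exp(-w1 / 17.0), 4e-5 * 17.0);
  double bxs = safe_ratio(3.5e-5 * w1, std::exp(w1 / 9.0) - 1.0, 3.5e-5 * 9.0);
  inf[8] = 1.0 / std::sqrt(1.0 + std::exp(-(V - 19.9) / 12.7));
  tau[8] = 0.5 / (axs + bxs);
  // ICaL gates
  double xd = V + 10.0;
  double e624 = std::exp(-xd / 6.24);
  tau[9] = (std::fabs(xd) < 1e-6)
    ? 1.0 / (0.035 * 6.24 * 2.0)
    : (1.0 - e624) / (0.035 * xd * (1.0 + e624));
  inf[9] = 1.0 / (1.0 + std::exp(-xd / 8.0));
  tau[10] = 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 * xd * xd) + 0.02);
  inf[10] = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));
  // SR w gate
  double yw = V - 7.9;
  double e5 = std::exp(-yw / 5.0);
  tau[11] = (std::fabs(yw) < 1e-6)
    ? 6.0 / (5.0 * 1.3)
    : 6.0 * (1.0 - e5) / ((1.0 + 0.3 * e5) * yw);
  inf[11] = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
}

struct Currents {
  double INa, IK1, Ito, IKur, IKr, IKs, ICaL, INaK, INaCa, IbNa, IbCa, IpCa;
  double Iion;
};

static Currents membrane_currents(const double* s, const Params& p) {
  Currents c;
  double V = s[0], Nai = s[16], Ki = s[17], Cai = s[18];
  double ENa = RTF * std::log(Nao / Nai);
  double EK  = RTF * std::log(Ko / Ki);
  double ECa = 0.5 * RTF * std::log(Cao / Cai);
  c.INa = p.gNa * s[1] * s[1] * s[1] * s[2] * s[3] * (V - ENa);
  c.IK1 = p.gK1 * (V - EK) / (1.0 + std::exp(0.07 * (V + 80.0)));
  c.Ito = p.gto * s[4] * s[4] * s[4] * s[5] * (V - EK);
  c.IKur = p.sKur * gkur_of_v(V) * s[6] * s[6] * s[6] * s[7] * (V - EK);
  c.IKr = gKr * s[8] * (V - EK) / (1.0 + std::exp((V + 15.0) / 22.4));
  c.IKs = gKs * s[9] * s[9] * (V - EK);
  c.ICaL = p.gCaL * s[10] * s[11] * s[12] * (V - 65.0);
  double sig = (std::exp(Nao / 67.3) - 1.0) / 7.0;
  double fnak = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RTF) +
                       0.0365 * sig * std::exp(-V / RTF));
  double r = KmNai / Nai;
  c.INaK = INaKmax * fnak * (1.0 / (1.0 + r * std::sqrt(r))) * Ko / (Ko + KmKo);
  double e1 = std::exp(gam * V / RTF), e2 = std::exp((gam - 1.0) * V / RTF);
  c.INaCa = p.INaCaMax *
    (e1 * Nai * Nai * Nai * Cao - e2 * Nao * Nao * Nao * Cai) /
    ((KmNa * KmNa * KmNa + Nao * Nao * Nao) * (KmCa + Cao) * (1.0 + ksat * e2));
  c.IbNa = gbNa * (V - ENa);
  c.IbCa = gbCa * (V - ECa);
  c.IpCa = IpCamax * Cai / (0.0005 + Cai);
  c.Iion = c.INa + c.IK1 + c.Ito + c.IKur + c.IKr + c.IKs + c.ICaL +
           c.INaK + c.INaCa + c.IbNa + c.IbCa + c.IpCa;
  return c;
}

// full right-hand side; used by the reference integrator and exported for tests
static void crn_derivs(const double* s, const Params& p, double Is, double* ds) {
  Currents c = membrane_currents(s, p);
  double inf[12], tau[12];
  gate_inf_tau(s[0], inf, tau);
  ds[0] = -(c.Iion + Is);
  static const int gidx[12] = {1,2,3,4,5,6,7,8,9,10,11,15};
  for (int g = 0; g < 12; ++g) ds[gidx[g]] = (inf[g] - s[gidx[g]]) / tau[g];
  double Cai = s[18], Caup = s[19], Carel = s[20];
  double fcainf = 1.0 / (1.0 + Cai / 0.00035);
  ds[12] = (fcainf - s[12]) / taufca;
  double Irel = krel * s[13] * s[13] * s[14] * s[15] * (Carel - Cai);
  double Fn = 1e-12 * Vrel * Irel -
              (5e-13 / Frd) * (0.5 * c.ICaL * Cm - 0.2 * c.INaCa * Cm);
  double uinf = 1.0 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));
  ds[13] = (uinf - s[13]) / tauu;
  double vinf = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 13.67e-16));
  double tauv = 1.91 + 2.09 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));
  ds[14] = (vinf - s[14]) / tauv;
  double Iup = p.IupMax / (1.0 + kup / Cai);
  double Iupleak = Caup * p.IupMax / Caupmax;
  double Itr = (Caup - Carel) / tautr;
  ds[16] = (-3.0 * c.INaK - 3.0 * c.INaCa - c.IbNa - c.INa) * Cm / (Frd * Vi);
  ds[17] = (2.0 * c.INaK - c.IK1 - c.Ito - c.IKur - c.IKr - c.IKs) * Cm / (Frd * Vi);
  double B1 = (2.0 * c.INaCa - c.IpCa - c.ICaL - c.IbCa) * Cm / (2.0 * Frd * Vi) +
              (Vup * (Iupleak - Iup) + Irel * Vrel) / Vi;
  double B2 = 1.0 + TRPNmax * KmTRPN / ((Cai + KmTRPN) * (Cai + KmTRPN)) +
              CMDNmax * KmCMDN / ((Cai + KmCMDN) * (Cai + KmCMDN));
  ds[18] = B1 / B2;
  ds[19] = Iup - Iupleak - Itr * Vrel / Vup;
  ds[20] = (Itr - Irel) /
           (1.0 + CSQNmax * KmCSQN / ((Carel + KmCSQN) * (Carel + KmCSQN)));
}

// one Rush-Larsen / forward-Euler step of a single cell (exact rate evaluation)
static void cell_step(double* s, const Params& p, double Is, double dt) {
  Currents c = membrane_currents(s, p);
  double inf[12], tau[12];
  gate_inf_tau(s[0], inf, tau);
  double Cai = s[18], Caup = s[19], Carel = s[20];
  double Irel = krel * s[13] * s[13] * s[14] * s[15] * (Carel - Cai);
  double Fn = 1e-12 * Vrel * Irel -
              (5e-13 / Frd) * (0.5 * c.ICaL * Cm - 0.2 * c.INaCa * Cm);
  double uinf = 1.0 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));
  double vinf = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 13.67e-16));
  double tauv = 1.91 + 2.09 / (1.0 + std::exp(-(Fn - 3.4175e-13) / 13.67e-16));
  double Iup = p.IupMax / (1.0 + kup / Cai);
  double Iupleak = Caup * p.IupMax / Caupmax;
  double Itr = (Caup - Carel) / tautr;
  // gates: exponential (Rush-Larsen) update
  static const int gidx[12] = {1,2,3,4,5,6,7,8,9,10,11,15};
  for (int g = 0; g < 12; ++g) {
    double e = std::exp(-dt / tau[g]);
    s[gidx[g]] = inf[g] + (s[gidx[g]] - inf[g]) * e;
  }
  double fcainf = 1.0 / (1.0 + Cai / 0.00035);
  s[12] = fcainf + (s[12] - fcainf) * std::exp(-dt / taufca);
  s[13] = uinf + (s[13] - uinf) * std::exp(-dt / tauu);
  s[14] = vinf + (s[14] - vinf) * std::exp(-dt / tauv);
  // concentrations: forward Euler
  s[16] += dt * (-3.0 * c.INaK - 3.0 * c.INaCa - c.IbNa - c.INa) * Cm / (Frd * Vi);
  s[17] += dt * (2.0 * c.INaK - c.IK1 - c.Ito - c.IKur - c.IKr - c.IKs) * Cm / (Frd * Vi);
  double B1 = (2.0 * c.INaCa - c.IpCa - c.ICaL - c.IbCa) * Cm / (2.0 * Frd * Vi) +
              (Vup * (Iupleak - Iup) + Irel * Vrel) / Vi;
  double B2 = 1.0 + TRPNmax * KmTRPN / ((Cai + KmTRPN) * (Cai + KmTRPN)) +
              CMDNmax * KmCMDN / ((Cai + KmCMDN) * (Cai + KmCMDN));
  s[18] += dt * B1 / B2;
  s[19] += dt * (Iup - Iupleak - Itr * Vrel / Vup);
  s[20] += dt * (Itr - Irel) /
           (1.0 + CSQNmax * KmCSQN / ((Carel + KmCSQN) * (Carel + KmCSQN)));
  s[0] += dt * (-(c.Iion + Is));
}

// [[Rcpp::export]]
NumericVector crn_resting_state_cpp() {
  // CRN 1998 published resting initial conditions
  NumericVector s(NSTATE);
  s[0] = -81.18; s[1] = 2.908e-3; s[2] = 9.649e-1; s[3] = 9.775e-1;
  s[4] = 3.043e-2; s[5] = 9.992e-1; s[6] = 4.966e-3; s[7] = 9.986e-1;
  s[8] = 3.296e-5; s[9] = 1.869e-2; s[10] = 1.367e-4; s[11] = 9.996e-1;
  s[12] = 7.755e-1; s[13] = 2.35e-112; s[14] = 1.0; s[15] = 9.992e-1;
  s[16] = 1.117e1; s[17] = 1.39e2; s[18] = 1.013e-4; s[19] = 1.488; s[20] = 1.488;
  return s;
}

// [[Rcpp::export]]
NumericVector crn_rhs_cpp(NumericVector state, List params, double stim) {
  if (state.size() != NSTATE) stop("state must have 21 elements");
  for (int i = 0; i < NSTATE; ++i)
    if (!R_finite(state[i])) stop("non-finite state: integration failure");
  Params p = params_from_list(params);
  NumericVector ds(NSTATE);
  crn_derivs(REAL(state), p, stim, REAL(ds));
  return ds;
}

// Single-cell integration with periodic current-pulse stimulation.
// Returns sampled V (and optionally full sampled state).
// [[Rcpp::export]]
List crn_cell_sim_cpp(NumericVector state0, List params, double duration,
                      double dt, double sample_dt, NumericVector stim_times,
                      double stim_dur, double stim_amp, bool full_state = false) {
  Params p = params_from_list(params);
  std::vector<double> s(REAL(state0), REAL(state0) + NSTATE);
  long nsteps = (long)std::llround(duration / dt);
  int sample_every = std::max(1, (int)std::lround(sample_dt / dt));
  int nsamp = (int)(nsteps / sample_every) + 1;
  NumericVector vout(nsamp), tout(nsamp);
  NumericMatrix sout = full_state ? NumericMatrix(NSTATE, nsamp) : NumericMatrix(0, 0);
  int k = 0;
  int nstim = stim_times.size();
  for (long step = 0; step <= nsteps; ++step) {
    double t = step * dt;
    if (step % sample_every == 0 && k < nsamp) {
      vout[k] = s[0]; tout[k] = t;
      if (full_state) for (int i = 0; i < NSTATE; ++i) sout(i, k) = s[i];
      ++k;
    }
    if (step == nsteps) break;
    double Is = 0.0;
    for (int i = 0; i < nstim; ++i)
      if (t >= stim_times[i] && t < stim_times[i] + stim_dur) { Is = stim_amp; break; }
    cell_step(s.data(), p, Is, dt);
    if (!std::isfinite(s[0]))
      stop("integration failure at t = %f ms (non-finite V)", t);
  }
  NumericVector fin(NSTATE);
  for (int i = 0; i < NSTATE; ++i) fin[i] = s[i];
  List out = List::create(_["t"] = tout, _["v"] = vout, _["state"] = fin);
  if (full_state) out["states"] = sout;
  return out;
}

// ---- tissue stepper with voltage lookup tables ------------------------------

struct Tables {
  double vmin, vmax, inv_dv;
  int n;
  // per V bin: 12 x (inf, rl) then gkur, k1f, krf, fnak, e1, e2  => 30 doubles
  std::vector<double> tab;
  static const int STRIDE = 30;
  void build(double dt) {
    vmin = -120.0; vmax = 80.0;
    double dv = 0.02;
    n = (int)((vmax - vmin) / dv) + 2;
    inv_dv = 1.0 / dv;
    tab.resize((size_t)n * STRIDE);
    double inf[12], tau[12];
    double sig = (std::exp(Nao / 67.3) - 1.0) / 7.0;
    for (int i = 0; i < n; ++i) {
      double V = vmin + i * dv;
      gate_inf_tau(V, inf, tau);
      double* row = &tab[(size_t)i * STRIDE];
      for (int g = 0; g < 12; ++g) {
        row[2 * g] = inf[g];
        row[2 * g + 1] = std::exp(-dt / tau[g]);
      }
      row[24] = gkur_of_v(V);
      row[25] = 1.0 / (1.0 + std::exp(0.07 * (V + 80.0)));
      row[26] = 1.0 / (1.0 + std::exp((V + 15.0) / 22.4));
      row[27] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RTF) +
                       0.0365 * sig * std::exp(-V / RTF));
      row[28] = std::exp(gam * V / RTF);
      row[29] = std::exp((gam - 1.0) * V / RTF);
    }
  }
};

// Full 2D monodomain simulation.
//
// protocol list fields:
//   pace_times (numeric, ms), pace_dur (ms), pace_amp (pA/pF),
//   pace_rows (int, number of rows at edge receiving the line stimulus),
//   cross_field (bool), reset_time (ms; <0 => auto trigger),
//   reset_value (mV), reset_delay (ms after auto trigger)
// stop_quiescent: terminate early once all V < -40 mV for 500 ms.
// [[Rcpp::export]]
List crn_tissue_sim_cpp(NumericMatrix state0, List params, int nx, int ny,
                        double dx, double Deff, LogicalVector lesion,
                        List protocol, double duration, double dt,
                        double sample_dt, bool record = true,
                        double record_from = 0.0,
                        bool stop_quiescent = false,
                        bool pure_diffusion = false,
                        double lesion_rest = -81.18) {
  const int nn = nx * ny;
  if (state0.nrow() != NSTATE || state0.ncol() != nn)
    stop("state0 must be 21 x (nx*ny)");
  if (lesion.size() != nn) stop("lesion mask length mismatch");
  Params p = params_from_list(params);
  const double cfl = dx * dx / (4.0 * Deff);
  if (dt > 0.8 * cfl + 1e-12)
    stop("CFL violation: dt = %f ms exceeds 0.8*dx^2/(4*Deff) = %f ms", dt, 0.8 * cfl);

  Tables tb; tb.build(dt);

  // state arrays, struct-of-arrays
  std::vector<std::vector<double> > S(NSTATE, std::vector<double>(nn));
  for (int i = 0; i < NSTATE; ++i)
    for (int j = 0; j < nn; ++j) S[i][j] = state0(i, j);
  std::vector<double> Vnew(nn), ENa(nn), EK(nn), ECa(nn);
  std::vector<unsigned char> les(nn);
  for (int j = 0; j < nn; ++j) les[j] = lesion[j] ? 1 : 0;
  for (int j = 0; j < nn; ++j) if (les[j]) S[0][j] = lesion_rest;

  NumericVector pace_times = protocol.containsElementNamed("pace_times")
    ? as<NumericVector>(protocol["pace_times"]) : NumericVector(0);
  double pace_dur = protocol.containsElementNamed("pace_dur")
    ? as<double>(protocol["pace_dur"]) : 2.0;
  double pace_amp = protocol.containsElementNamed("pace_amp")
    ? as<double>(protocol["pace_amp"]) : -30.0;
  int pace_rows = protocol.containsElementNamed("pace_rows")
    ? as<int>(protocol["pace_rows"]) : 2;
  bool cross_field = protocol.containsElementNamed("cross_field")
    ? as<bool>(protocol["cross_field"]) : false;
  double reset_time = protocol.containsElementNamed("reset_time")
    ? as<double>(protocol["reset_time"]) : -1.0;
  double reset_value = protocol.containsElementNamed("reset_value")
    ? as<double>(protocol["reset_value"]) : 0.0;
  double reset_delay = protocol.containsElementNamed("reset_delay")
    ? as<double>(protocol["reset_delay"]) : 0.0;

  long nsteps = (long)std::llround(duration / dt);
  int sample_every = std::max(1, (int)std::lround(sample_dt / dt));
  long rec_from_step = (long)std::llround(record_from / dt);
  int nsamp = 0;
  if (record) {
    for (long st = 0; st <= nsteps; ++st)
      if (st >= rec_from_step && (st - rec_from_step) % sample_every == 0) ++nsamp;
  }
  NumericMatrix vout = record ? NumericMatrix(nn, nsamp) : NumericMatrix(0, 0);
  NumericVector tout(record ? nsamp : 0);

  double applied_reset = NA_REAL;   // time at which cross-field reset fired
  double trigger_t = (reset_time >= 0.0) ? reset_time : -1.0;
  bool reset_done = !cross_field;
  // auto-trigger: the paced edge has repolarized while the wave still crosses
  // the sheet, i.e. the planar wave is in its repolarizing phase
  int mon_row = 2;                  // node near the paced edge
  int mon_col = nx / 4;             // in the non-reset (left) half
  bool mon_was_active = false;

  double quiesc_since = -1.0;
  double stop_time = NA_REAL;
  int k = 0;
  const double* trow = tb.tab.data();

  for (long step = 0; step <= nsteps; ++step) {
    double t = step * dt;
    if (record && step >= rec_from_step &&
        (step - rec_from_step) % sample_every == 0 && k < nsamp) {
      double* col = &vout(0, k);
      std::memcpy(col, S[0].data(), nn * sizeof(double));
      tout[k] = t;
      ++k;
    }
    if (step == nsteps) break;

    // update reversal potentials every 25 steps (concentrations drift slowly)
    if (step % 25 == 0) {
      for (int j = 0; j < nn; ++j) {
        ENa[j] = RTF * std::log(Nao / S[16][j]);
        EK[j] = RTF * std::log(Ko / S[17][j]);
        ECa[j] = 0.5 * RTF * std::log(Cao / S[18][j]);
      }
    }

    // cross-field auto trigger: paced-edge node depolarizes then recovers
    if (cross_field && !reset_done && trigger_t < 0.0) {
      double vm = S[0][mon_row * nx + mon_col];
      if (!mon_was_active && vm > -20.0) mon_was_active = true;
      else if (mon_was_active && vm < -70.0) trigger_t = t + reset_delay;
    }
    if (cross_field && !reset_done && trigger_t >= 0.0 && t >= trigger_t) {
      for (int r = 0; r < ny; ++r)
        for (int cix = nx / 2; cix < nx; ++cix)
          if (!les[r * nx + cix]) S[0][r * nx + cix] = reset_value;
      applied_reset = t;
      reset_done = true;
    }

    // stimulus window?
    double Is_now = 0.0;
    for (int i = 0; i < pace_times.size(); ++i)
      if (t >= pace_times[i] && t < pace_times[i] + pace_dur) { Is_now = pace_amp; break; }

    // diffusion pass (no-flux boundaries via mirroring)
    const double* V = S[0].data();
    const double dcoef = dt * Deff / (dx * dx);
    for (int r = 0; r < ny; ++r) {
      int rm = (r == 0) ? 0 : r - 1, rp = (r == ny - 1) ? ny - 1 : r + 1;
      const double* Vr = V + (size_t)r * nx;
      const double* Vm = V + (size_t)rm * nx;
      const double* Vp = V + (size_t)rp * nx;
      double* out = Vnew.data() + (size_t)r * nx;
      for (int cix = 0; cix < nx; ++cix) {
        int cm = (cix == 0) ? 0 : cix - 1, cp = (cix == nx - 1) ? nx - 1 : cix + 1;
        double lap = Vm[cix] + Vp[cix] + Vr[cm] + Vr[cp] - 4.0 * Vr[cix];
        out[cix] = Vr[cix] + dcoef * lap;
      }
    }

    if (!pure_diffusion) {
      // ionic pass
      for (int j = 0; j < nn; ++j) {
        if (les[j]) { Vnew[j] = lesion_rest; continue; }
        double Vj = V[j];
        // table lookup with linear interpolation
        double pos = (Vj - tb.vmin) * tb.inv_dv;
        if (pos < 0.0) pos = 0.0;
        if (pos > tb.n - 2) pos = tb.n - 2;
        int i0 = (int)pos;
        double fr = pos - i0;
        const double* r0 = trow + (size_t)i0 * Tables::STRIDE;
        const double* r1 = r0 + Tables::STRIDE;
        double L[30];
        for (int q = 0; q < 30; ++q) L[q] = r0[q] + fr * (r1[q] - r0[q]);

        double m = S[1][j], h = S[2][j], jj = S[3][j];
        double oa = S[4][j], oi = S[5][j], ua = S[6][j], ui = S[7][j];
        double xr = S[8][j], xs = S[9][j], d = S[10][j], f = S[11][j];
        double fca = S[12][j], uu = S[13][j], vv = S[14][j], ww = S[15][j];
        double Nai = S[16][j], Cai = S[18][j], Caup = S[19][j], Carel = S[20][j];

        double INa = p.gNa * m * m * m * h * jj * (Vj - ENa[j]);
        double IK1 = p.gK1 * (Vj - EK[j]) * L[25];
        double Ito = p.gto * oa * oa * oa * oi * (Vj - EK[j]);
        double IKur = p.sKur * L[24] * ua * ua * ua * ui * (Vj - EK[j]);
        double IKr = gKr * xr * L[26] * (Vj - EK[j]);
        double IKs = gKs * xs * xs * (Vj - EK[j]);
        double ICaL = p.gCaL * d * f * fca * (Vj - 65.0);
        double rr = KmNai / Nai;
        double INaK = INaKmax * L[27] * (1.0 / (1.0 + rr * std::sqrt(rr))) * Ko / (Ko + KmKo);
        double INaCa = p.INaCaMax *
          (L[28] * Nai * Nai * Nai * Cao - L[29] * Nao * Nao * Nao * Cai) /
          ((KmNa * KmNa * KmNa + Nao * Nao * Nao) * (KmCa + Cao) * (1.0 + ksat * L[29]));
        double IbNa = gbNa * (Vj - ENa[j]);
        double IbCa = gbCa * (Vj - ECa[j]);
        double IpCa = IpCamax * Cai / (0.0005 + Cai);
        double Iion = INa + IK1 + Ito + IKur + IKr + IKs + ICaL + INaK + INaCa +
                      IbNa + IbCa + IpCa;

        double Irel = krel * uu * uu * vv * ww * (Carel - Cai);
        double Fn = 1e-12 * Vrel * Irel -
                    (5e-13 / Frd) * (0.5 * ICaL * Cm - 0.2 * INaCa * Cm);
        double efn = std::exp(-(Fn - 3.4175e-13) / 13.67e-16);
        double uinf = 1.0 / (1.0 + efn);
        double vinf = 1.0 - 1.0 / (1.0 + std::exp(-(Fn - 6.835e-14) / 13.67e-16));
        double tauv = 1.91 + 2.09 * uinf;
        double Iup = p.IupMax / (1.0 + kup / Cai);
        double Iupleak = Caup * p.IupMax / Caupmax;
        double Itr = (Caup - Carel) / tautr;

        // gates (Rush-Larsen via tabulated exp factors)
        S[1][j] = L[0] + (m - L[0]) * L[1];
        S[2][j] = L[2] + (h - L[2]) * L[3];
        S[3][j] = L[4] + (jj - L[4]) * L[5];
        S[4][j] = L[6] + (oa - L[6]) * L[7];
        S[5][j] = L[8] + (oi - L[8]) * L[9];
        S[6][j] = L[10] + (ua - L[10]) * L[11];
        S[7][j] = L[12] + (ui - L[12]) * L[13];
        S[8][j] = L[14] + (xr - L[14]) * L[15];
        S[9][j] = L[16] + (xs - L[16]) * L[17];
        S[10][j] = L[18] + (d - L[18]) * L[19];
        S[11][j] = L[20] + (f - L[20]) * L[21];
        S[15][j] = L[22] + (ww - L[22]) * L[23];
        double fcainf = 1.0 / (1.0 + Cai / 0.00035);
        S[12][j] = fcainf + (fca - fcainf) * std::exp(-dt / taufca);
        S[13][j] = uinf + (uu - uinf) * std::exp(-dt / tauu);
        S[14][j] = vinf + (vv - vinf) * std::exp(-dt / tauv);

        S[16][j] += dt * (-3.0 * INaK - 3.0 * INaCa - IbNa - INa) * Cm / (Frd * Vi);
        S[17][j] += dt * (2.0 * INaK - IK1 - Ito - IKur - IKr - IKs) * Cm / (Frd * Vi);
        double B1 = (2.0 * INaCa - IpCa - ICaL - IbCa) * Cm / (2.0 * Frd * Vi) +
                    (Vup * (Iupleak - Iup) + Irel * Vrel) / Vi;
        double B2 = 1.0 + TRPNmax * KmTRPN / ((Cai + KmTRPN) * (Cai + KmTRPN)) +
                    CMDNmax * KmCMDN / ((Cai + KmCMDN) * (Cai + KmCMDN));
        S[18][j] += dt * B1 / B2;
        S[19][j] += dt * (Iup - Iupleak - Itr * Vrel / Vup);
        S[20][j] += dt * (Itr - Irel) /
                    (1.0 + CSQNmax * KmCSQN / ((Carel + KmCSQN) * (Carel + KmCSQN)));

        double Is = 0.0;
        if (Is_now != 0.0 && (j / nx) < pace_rows) Is = Is_now;
        Vnew[j] -= dt * (Iion + Is);
      }
    }
    std::swap(S[0], Vnew);

    if (step % 200 == 0) {
      // integration-health and quiescence checks every 10 ms at dt = 0.05
      double vmaxv = -1e9;
      bool bad = false;
      for (int j = 0; j < nn; ++j) {
        double vj = S[0][j];
        if (!std::isfinite(vj)) { bad = true; break; }
        if (vj > vmaxv) vmaxv = vj;
      }
      if (bad) stop("integration failure at t = %f ms (non-finite field)", t);
      if (stop_quiescent) {
        if (vmaxv < -40.0) {
          if (quiesc_since < 0.0) quiesc_since = t;
          if (t - quiesc_since >= 500.0) { stop_time = t; break; }
        } else quiesc_since = -1.0;
      }
      Rcpp::checkUserInterrupt();
    }
  }

  NumericMatrix fin(NSTATE, nn);
  for (int i = 0; i < NSTATE; ++i)
    for (int j = 0; j < nn; ++j) fin(i, j) = S[i][j];
  if (record && k < nsamp) {
    vout = vout(_, Range(0, std::max(0, k - 1)));
    tout = head(tout, k);
  }
  return List::create(_["v"] = vout, _["t"] = tout, _["state"] = fin,
                      _["reset_time"] = applied_reset,
                      _["stop_time"] = stop_time,
                      _["quiescent_since"] = quiesc_since);
}
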