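// Explicit monodomain / single-cell engine for the Courtemanche-Ramirez-Nattel
// (CRN) human atrial myocyte model with state-dependent IKur block.
//
// Numerics: Rush-Larsen (exact exponential relaxation) for voltage-gated
// variables, forward Euler for Vm, concentrations and the Ca-release gates
// whose time constants are far above dt; centered-difference Laplacian with
// no-flux (mirrored) boundaries.  All voltage-dependent coefficients are
// tabulated once per call on a 0.05 mV grid and linearly interpolated, which
// keeps the per-node step free of transcendental calls except for the
// Ca-release Fn sigmoids and the Ca Nernst potential.
//
// Units: mV, ms, pA/pF, mM, mm.  Currents named i_* are per-capacitance.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---- state indexing (one column per node, 22 rows) ----
enum StateIdx { iV = 0, iM, iH, iJ, iOA, iOI, iUA, iUI, iXR, iXS,
                iD, iF, iFCA, iU, iVg, iW, iNAI, iCAI, iKI, iCAREL, iCAUP,
                iY, NSTATE };

// ---- physical constants (CRN) ----
static const double Rgas = 8.3143, Temp = 310.0, Far = 96.4867;
static const double RTF  = Rgas * Temp / Far;       // 26.7128 mV
static const double Cm   = 100.0;                   // pF
static const double Vi_  = 13668.0, Vup_ = 1109.52, Vrel_ = 96.48; // um^3
static const double Ko = 5.4, Nao = 140.0, Cao = 1.8;              // mM
static const double krel = 30.0, iupmax = 0.005, kup = 0.00092, caupmax = 15.0;
static const double cmdnmax = 0.05, trpnmax = 0.07, csqnmax = 10.0;
static const double kmcmdn = 0.00238, kmtrpn = 0.0005, kmcsqn = 0.8;
static const double kmnai = 10.0, kmko = 1.5;
static const double kmna = 87.5, kmca = 1.38, ksat = 0.1, gam = 0.35;
static const double tautr = 180.0, tauu = 8.0, taufca = 2.0;
static const double KQ10 = 3.0;

static inline double cexp(double x) {
  if (x >  80.0) x =  80.0;
  if (x < -80.0) x = -80.0;
  return std::exp(x);
}

// ---- voltage-dependent rate helpers (used only to build the table) ----
struct Rates { double inf, tau; };

static Rates rate_m(double V) {
  double a = (std::fabs(V + 47.13) < 1e-7)
    ? 3.2 : 0.32 * (V + 47.13) / (1.0 - std::exp(-0.1 * (V + 47.13)));
  double b = 0.08 * std::exp(-V / 11.0);
  return { a / (a + b), 1.0 / (a + b) };
}
static Rates rate_h(double V) {
  double a, b;
  if (V < -40.0) {
    a = 0.135 * std::exp((V + 80.0) / -6.8);
    b = 3.56 * std::exp(0.079 * V) + 3.1e5 * std::exp(0.35 * V);
  } else {
    a = 0.0;
    b = 1.0 / (0.13 * (1.0 + std::exp((V + 10.66) / -11.1)));
  }
  return { a / (a + b), 1.0 / (a + b) };
}
static Rates rate_j(double V) {
  double a, b;
  if (V < -40.0) {
    a = (-1.2714e5 * std::exp(0.2444 * V) - 3.474e-5 * std::exp(-0.04391 * V))
        * (V + 37.78) / (1.0 + std::exp(0.311 * (V + 79.23)));
    b = 0.1212 * std::exp(-0.01052 * V) / (1.0 + std::exp(-0.1378 * (V + 40.14)));
  } else {
    a = 0.0;
    b = 0.3 * std::exp(-2.535e-7 * V) / (1.0 + std::exp(-0.1 * (V + 32.0)));
  }
  return { a / (a + b), 1.0 / (a + b) };
}
static Rates rate_oa(double V) {
  double a = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  double b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  double inf = 1.0 / (1.0 + std::exp(-(V + 20.47) / 17.54));
  return { inf, 1.0 / ((a + b) * KQ10) };
}
static Rates rate_oi(double V) {
  double a = 1.0 / (18.53 + std::exp((V + 113.7) / 10.95));
  double b = 1.0 / (35.56 + std::exp(-(V + 1.26) / 7.44));
  double inf = 1.0 / (1.0 + std::exp((V + 43.1) / 5.3));
  return { inf, 1.0 / ((a + b) * KQ10) };
}
static Rates rate_ua(double V) {
  double a = 0.65 / (std::exp(-(V + 10.0) / 8.5) + std::exp(-(V - 30.0) / 59.0));
  double b = 0.65 / (2.5 + std::exp((V + 82.0) / 17.0));
  double inf = 1.0 / (1.0 + std::exp(-(V + 30.3) / 9.6));
  return { inf, 1.0 / ((a + b) * KQ10) };
}
static Rates rate_ui(double V) {
  double a = 1.0 / (21.0 + std::exp(-(V - 185.0) / 28.0));
  double b = std::exp((V - 158.0) / 16.0);
  double inf = 1.0 / (1.0 + std::exp((V - 99.45) / 27.48));
  return { inf, 1.0 / ((a + b) * KQ10) };
}
static Rates rate_xr(double V) {
  double a = (std::fabs(V + 14.1) < 1e-7)
    ? 0.0015 : 0.0003 * (V + 14.1) / (1.0 - std::exp(-(V + 14.1) / 5.0));
  double b = (std::fabs(V - 3.3328) < 1e-7)
    ? 3.7836118e-4
    : 7.3898e-5 * (V - 3.3328) / (std::exp((V - 3.3328) / 5.1237) - 1.0);
  double inf = 1.0 / (1.0 + std::exp(-(V + 14.1) / 6.5));
  return { inf, 1.0 / (a + b) };
}
static Rates rate_xs(double V) {
  double a = (std::fabs(V - 19.9) < 1e-7)
    ? 0.00068 : 4e-5 * (V - 19.9) / (1.0 - std::exp(-(V - 19.9) / 17.0));
  double b = (std::fabs(V - 19.9) < 1e-7)
    ? 0.000315 : 3.5e-5 * (V - 19.9) / (std::exp((V - 19.9) / 9.0) - 1.0);
  double inf = 1.0 / std::sqrt(1.0 + std::exp(-(V - 19.9) / 12.7));
  return { inf, 0.5 / (a + b) };
}
static Rates rate_d(double V) {
  double inf = 1.0 / (1.0 + std::exp(-(V + 10.0) / 8.0));
  double tau;
  if (std::fabs(V + 10.0) < 1e-7) tau = 1.0 / (6.24 * 0.035 * 2.0);
  else {
    double e = std::exp(-(V + 10.0) / 6.24);
    tau = (1.0 - e) / (0.035 * (V + 10.0) * (1.0 + e));
  }
  return { inf, tau };
}
static Rates rate_f(double V) {
  double inf = 1.0 / (1.0 + std::exp((V + 28.0) / 6.9));
  double tau = 9.0 / (0.0197 * std::exp(-0.0337 * 0.0337 * (V + 10.0) * (V + 10.0)) + 0.02);
  return { inf, tau };
}
static Rates rate_w(double V) {
  double inf = 1.0 - 1.0 / (1.0 + std::exp(-(V - 40.0) / 17.0));
  double tau;
  if (std::fabs(V - 7.9) < 1e-7) tau = 6.0 * 0.2 / 1.3;
  else {
    double e = std::exp(-(V - 7.9) / 5.0);
    tau = 6.0 * (1.0 - e) / ((1.0 + 0.3 * e) * (V - 7.9));
  }
  return { inf, tau };
}

// ---- lookup table ----
static const double LUT_V0 = -120.0, LUT_V1 = 80.0, LUT_DV = 0.05;
static const int    LUT_N  = (int)((LUT_V1 - LUT_V0) / LUT_DV) + 1;
static const int    LUT_W  = 32;   // doubles per row

enum LutCol { cMI, cME, cHI, cHE, cJI, cJE, cOAI, cOAE, cOII, cOIE,
              cUAI, cUAE, cUII, cUIE, cXRI, cXRE, cXSI, cXSE,
              cDI, cDE, cFI, cFE, cWI, cWE,
              cGKUR, cK1D, cKRR, cFNAK, cNC1, cNC2, cYI, cYE };

struct Compound {
  int mode;            // 0 none, 1 dynamic, 2 tonic
  double tau_on, tau_rec, vhalf, slope, maxblock, tonic, drug_on;
};

static void build_lut(std::vector<double>& lut, double dt, const Compound& cp) {
  lut.resize((size_t)LUT_N * LUT_W);
  double signak = (std::exp(Nao / 67.3) - 1.0) / 7.0;
  for (int k = 0; k < LUT_N; ++k) {
    double V = LUT_V0 + k * LUT_DV;
    double* r = &lut[(size_t)k * LUT_W];
    Rates rr;
    rr = rate_m(V);  r[cMI]  = rr.inf; r[cME]  = std::exp(-dt / rr.tau);
    rr = rate_h(V);  r[cHI]  = rr.inf; r[cHE]  = std::exp(-dt / rr.tau);
    rr = rate_j(V);  r[cJI]  = rr.inf; r[cJE]  = std::exp(-dt / rr.tau);
    rr = rate_oa(V); r[cOAI] = rr.inf; r[cOAE] = std::exp(-dt / rr.tau);
    rr = rate_oi(V); r[cOII] = rr.inf; r[cOIE] = std::exp(-dt / rr.tau);
    rr = rate_ua(V); r[cUAI] = rr.inf; r[cUAE] = std::exp(-dt / rr.tau);
    rr = rate_ui(V); r[cUII] = rr.inf; r[cUIE] = std::exp(-dt / rr.tau);
    rr = rate_xr(V); r[cXRI] = rr.inf; r[cXRE] = std::exp(-dt / rr.tau);
    rr = rate_xs(V); r[cXSI] = rr.inf; r[cXSE] = std::exp(-dt / rr.tau);
    rr = rate_d(V);  r[cDI]  = rr.inf; r[cDE]  = std::exp(-dt / rr.tau);
    rr = rate_f(V);  r[cFI]  = rr.inf; r[cFE]  = std::exp(-dt / rr.tau);
    rr = rate_w(V);  r[cWI]  = rr.inf; r[cWE]  = std::exp(-dt / rr.tau);
    r[cGKUR] = 0.005 + 0.05 / (1.0 + std::exp(-(V - 15.0) / 13.0));
    r[cK1D]  = 1.0 / (1.0 + std::exp(0.07 * (V + 80.0)));
    r[cKRR]  = 1.0 / (1.0 + std::exp((V + 15.0) / 22.4));
    r[cFNAK] = 1.0 / (1.0 + 0.1245 * std::exp(-0.1 * V / RTF)
                          + 0.0365 * signak * std::exp(-V / RTF));
    r[cNC1]  = std::exp(gam * V / RTF);
    r[cNC2]  = std::exp((gam - 1.0) * V / RTF);
    if (cp.mode == 1) {
      double s   = 1.0 / (1.0 + std::exp(-(V - cp.vhalf) / cp.slope));
      double tau = cp.tau_rec + (cp.tau_on - cp.tau_rec) * s;
      r[cYI] = 1.0 - cp.maxblock * s;
      r[cYE] = std::exp(-dt / tau);
    } else { r[cYI] = 1.0; r[cYE] = 1.0; }
  }
}

struct Conduct {   // maximal conductances / scalers (pA/pF based)
  double gna, gk1, gto, gkur_scale, gkr, gks, gcal, gbca, gbna;
  double inakmax, inacamax, ipcamax;
};

// per-node Nernst cache: Na/K drift over seconds; Ca is refreshed on a 2%
// relative change (enters only the small background Ca current)
struct NernstCache { double ena, ek, eca, nai_ref, ki_ref, cai_ref; };

// logistic sigma(a) = 1/(1+exp(-a)) tabulated on a in [-40, 40], step 0.02
static const double SIG_A0 = -40.0, SIG_DA = 0.02;
static const int SIG_N = (int)(80.0 / SIG_DA) + 1;
static std::vector<double> sig_tab;
static void build_sig_tab() {
  if (!sig_tab.empty()) return;
  sig_tab.resize(SIG_N);
  for (int i = 0; i < SIG_N; ++i)
    sig_tab[i] = 1.0 / (1.0 + std::exp(-(SIG_A0 + i * SIG_DA)));
}
static inline double sig_lut(double a) {
  if (a <= SIG_A0) return sig_tab[0];
  double p = (a - SIG_A0) / SIG_DA;
  if (p >= SIG_N - 1.001) return sig_tab[SIG_N - 1];
  int k = (int)p;
  double fr = p - k;
  return sig_tab[k] + fr * (sig_tab[k + 1] - sig_tab[k]);
}

// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List sim_run_cpp(NumericMatrix state, List pars, double dt, double t0,
                 double duration, List stims, List record) {
  const int n = state.ncol();
  if (state.nrow() != NSTATE) stop("state must have %d rows", NSTATE);
  const int nx = as<int>(pars["nx"]), ny = as<int>(pars["ny"]);
  if (nx * ny != n) stop("nx*ny must equal number of state columns");
  const double dx = as<double>(pars["dx"]);
  const double Dc = as<double>(pars["D"]);

  Conduct g;
  g.gna = as<double>(pars["g_na"]);   g.gk1 = as<double>(pars["g_k1"]);
  g.gto = as<double>(pars["g_to"]);   g.gkur_scale = as<double>(pars["g_kur_scale"]);
  g.gkr = as<double>(pars["g_kr"]);   g.gks = as<double>(pars["g_ks"]);
  g.gcal = as<double>(pars["g_cal"]); g.gbca = as<double>(pars["g_bca"]);
  g.gbna = as<double>(pars["g_bna"]);
  g.inakmax = as<double>(pars["i_nak_max"]);
  g.inacamax = as<double>(pars["i_naca_max"]);
  g.ipcamax = as<double>(pars["i_pca_max"]);

  Compound cp;
  cp.mode = as<int>(pars["compound_mode"]);
  cp.tau_on  = as<double>(pars["tau_onset"]);
  cp.tau_rec = as<double>(pars["tau_recovery"]);
  cp.vhalf   = as<double>(pars["v_half"]);
  cp.slope   = as<double>(pars["slope"]);
  cp.maxblock = as<double>(pars["max_block"]);
  cp.tonic   = as<double>(pars["tonic_level"]);
  cp.drug_on = as<double>(pars["drug_on"]);

  std::vector<double> lut;
  build_lut(lut, dt, cp);
  build_sig_tab();
  const double efca = std::exp(-dt / taufca);
  const double naca_den0 = (kmna * kmna * kmna + Nao * Nao * Nao) * (kmca + Cao);

  // stimuli
  NumericVector st_on = stims["t_on"], st_dur = stims["duration"],
                st_amp = stims["amplitude"];
  List st_nodes = stims["nodes"];       // 0-based index vectors
  const int nstim = st_on.size();

  // recording setup
  IntegerVector probes = record["probes"];          // 0-based
  const double sample_dt = as<double>(record["sample_dt"]);
  const double frame_dt  = as<double>(record["frame_dt"]); // <=0: none
  const bool   rec_h     = as<bool>(record["record_h"]);
  NumericVector ecg_w    = record["ecg_w"];          // length n or 0
  const bool   rec_refr  = as<bool>(record["record_refr"]);

  const long nsteps  = (long)std::llround(duration / dt);
  const long samp_ev = std::max(1L, (long)std::llround(sample_dt / dt));
  const long nsamp   = nsteps / samp_ev + 1;
  const long frame_ev = frame_dt > 0 ? std::max(1L, (long)std::llround(frame_dt / dt)) : 0;
  const long nframes  = frame_ev > 0 ? nsteps / frame_ev + 1 : 0;

  NumericMatrix probe_vm(nsamp, probes.size());
  NumericVector samp_t(nsamp), refr_pct(rec_refr ? nsamp : 0),
                ecg(ecg_w.size() == n ? nsamp : 0);
  NumericVector frames_t(nframes);
  NumericVector frames_vm(nframes > 0 ? (R_xlen_t)nframes * n : 0);
  NumericVector frames_h((nframes > 0 && rec_h) ? (R_xlen_t)nframes * n : 0);

  // working arrays (flat, node-major state copy for cache locality)
  std::vector<double> S((size_t)n * NSTATE);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < NSTATE; ++k) S[(size_t)i * NSTATE + k] = state(k, i);
  std::vector<double> lap(n, 0.0), istim(n, 0.0);
  std::vector<NernstCache> nc(n);
  for (int i = 0; i < n; ++i) {
    double nai = S[(size_t)i * NSTATE + iNAI], ki = S[(size_t)i * NSTATE + iKI];
    double cai = S[(size_t)i * NSTATE + iCAI];
    nc[i].ena = RTF * std::log(Nao / nai); nc[i].nai_ref = nai;
    nc[i].ek  = RTF * std::log(Ko / ki);   nc[i].ki_ref  = ki;
    nc[i].eca = 0.5 * RTF * std::log(Cao / cai); nc[i].cai_ref = cai;
  }

  const double inv_dx2 = (Dc > 0.0 && n > 1) ? 1.0 / (dx * dx) : 0.0;
  long isamp = 0, iframe = 0;

  for (long step = 0; step <= nsteps; ++step) {
    const double t = t0 + step * dt;

    // ---- diffusion (also the distributed source current for the pseudo-ECG)
    if (inv_dx2 > 0.0) {
      // zero-gradient ghost nodes (ghost = boundary node): the summed
      // Laplacian telescopes to zero, so diffusion conserves total charge
      if (ny == 1) {
        for (int x = 0; x < nx; ++x) {
          const double vl = S[(size_t)(x > 0 ? x - 1 : 0) * NSTATE + iV];
          const double vr = S[(size_t)(x < nx - 1 ? x + 1 : nx - 1) * NSTATE + iV];
          lap[x] = (vl + vr - 2.0 * S[(size_t)x * NSTATE + iV]) * inv_dx2;
        }
      } else {
        for (int y = 0; y < ny; ++y) {
          const int ym = (y > 0 ? y - 1 : 0), yp = (y < ny - 1 ? y + 1 : ny - 1);
          for (int x = 0; x < nx; ++x) {
            const int i = x + nx * y;
            const int xm = (x > 0 ? x - 1 : 0), xp = (x < nx - 1 ? x + 1 : nx - 1);
            lap[i] = (S[(size_t)(xm + nx * y) * NSTATE + iV]
                    + S[(size_t)(xp + nx * y) * NSTATE + iV]
                    + S[(size_t)(x + nx * ym) * NSTATE + iV]
                    + S[(size_t)(x + nx * yp) * NSTATE + iV]
                    - 4.0 * S[(size_t)i * NSTATE + iV]) * inv_dx2;
          }
        }
      }
    }

    // ---- recording (state BEFORE this step's update, time t)
    const bool do_samp  = (step % samp_ev == 0);
    const bool do_frame = (frame_ev > 0) && (step % frame_ev == 0);
    if (do_samp && isamp < nsamp) {
      samp_t[isamp] = t;
      for (int p = 0; p < probes.size(); ++p)
        probe_vm(isamp, p) = S[(size_t)probes[p] * NSTATE + iV];
      if (rec_refr) {
        int cnt = 0;
        for (int i = 0; i < n; ++i) if (S[(size_t)i * NSTATE + iH] < 0.5) ++cnt;
        refr_pct[isamp] = 100.0 * cnt / n;
      }
      if (ecg.size() > 0) {
        double s = 0.0;
        for (int i = 0; i < n; ++i) s += ecg_w[i] * Dc * lap[i];
        ecg[isamp] = s;
      }
      ++isamp;
    }
    if (do_frame && iframe < nframes) {
      frames_t[iframe] = t;
      double* fv = &frames_vm[(R_xlen_t)iframe * n];
      for (int i = 0; i < n; ++i) fv[i] = S[(size_t)i * NSTATE + iV];
      if (rec_h) {
        double* fh = &frames_h[(R_xlen_t)iframe * n];
        for (int i = 0; i < n; ++i) fh[i] = S[(size_t)i * NSTATE + iH];
      }
      ++iframe;
    }
    if (step == nsteps) break;

    // ---- stimulus currents for this step
    bool any_stim = false;
    for (int s = 0; s < nstim; ++s)
      if (t >= st_on[s] && t < st_on[s] + st_dur[s]) { any_stim = true; break; }
    if (any_stim) {
      std::fill(istim.begin(), istim.end(), 0.0);
      for (int s = 0; s < nstim; ++s) {
        if (t >= st_on[s] && t < st_on[s] + st_dur[s]) {
          IntegerVector nodes = st_nodes[s];
          for (int k = 0; k < nodes.size(); ++k) istim[nodes[k]] += st_amp[s];
        }
      }
    }

    const bool drug_active = (cp.mode != 0) && (t >= cp.drug_on);

    // ---- reaction update per node
    for (int i = 0; i < n; ++i) {
      double* s = &S[(size_t)i * NSTATE];
      double V = s[iV];
      if (V > 200.0 || V < -200.0 || !std::isfinite(V))
        stop("simulation diverged: Vm = %.2f mV at node %d, t = %.3f ms", V, i + 1, t);

      // LUT row interpolation
      double vp = (V - LUT_V0) / LUT_DV;
      if (vp < 0.0) vp = 0.0;
      if (vp > LUT_N - 1.001) vp = LUT_N - 1.001;
      const int k0 = (int)vp;
      const double fr = vp - k0;
      const double* r0 = &lut[(size_t)k0 * LUT_W];
      const double* r1 = r0 + LUT_W;
#define LI(c) (r0[c] + fr * (r1[c] - r0[c]))
#define GATE(idx, ci, ce) { const double gi = LI(ci); \
        s[idx] = gi + (s[idx] - gi) * LI(ce); }

      // Rush-Larsen gate updates
      GATE(iM, cMI, cME);   GATE(iH, cHI, cHE);   GATE(iJ, cJI, cJE);
      GATE(iOA, cOAI, cOAE); GATE(iOI, cOII, cOIE);
      GATE(iUA, cUAI, cUAE); GATE(iUI, cUII, cUIE);
      GATE(iXR, cXRI, cXRE); GATE(iXS, cXSI, cXSE);
      GATE(iD, cDI, cDE);   GATE(iF, cFI, cFE);   GATE(iW, cWI, cWE);
#undef GATE

      const double nai = s[iNAI], cai = s[iCAI], ki = s[iKI];

      // slow Nernst refresh (Na, K drift over seconds), Ca exact
      NernstCache& c = nc[i];
      if (std::fabs(nai - c.nai_ref) > 1e-3) {
        c.ena = RTF * std::log(Nao / nai); c.nai_ref = nai;
      }
      if (std::fabs(ki - c.ki_ref) > 1e-3) {
        c.ek = RTF * std::log(Ko / ki); c.ki_ref = ki;
      }
      if (std::fabs(cai - c.cai_ref) > 0.02 * c.cai_ref) {
        c.eca = 0.5 * RTF * std::log(Cao / cai); c.cai_ref = cai;
      }
      const double eca = c.eca;

      // IKur block variable
      double y = 1.0;
      if (cp.mode == 2) { y = drug_active ? cp.tonic : 1.0; s[iY] = y; }
      else if (cp.mode == 1) {
        if (drug_active) s[iY] = LI(cYI) + (s[iY] - LI(cYI)) * LI(cYE);
        else s[iY] = 1.0;
        y = s[iY];
      }

      // fCa gate (Ca-dependent steady state, tau = 2 ms)
      const double fcainf = 1.0 / (1.0 + cai / 0.00035);
      s[iFCA] = fcainf + (s[iFCA] - fcainf) * efca;

      // ---- currents (pA/pF)
      const double vek = V - c.ek;
      const double m3 = s[iM] * s[iM] * s[iM];
      const double ina  = g.gna * m3 * s[iH] * s[iJ] * (V - c.ena);
      const double ik1  = g.gk1 * vek * LI(cK1D);
      const double oa3 = s[iOA] * s[iOA] * s[iOA];
      const double ito  = g.gto * oa3 * s[iOI] * vek;
      const double ua3 = s[iUA] * s[iUA] * s[iUA];
      const double ikur = g.gkur_scale * LI(cGKUR) * ua3 * s[iUI] * vek * y;
      const double ikr  = g.gkr * s[iXR] * vek * LI(cKRR);
      const double iks  = g.gks * s[iXS] * s[iXS] * vek;
      const double ical = g.gcal * s[iD] * s[iF] * s[iFCA] * (V - 65.0);
      const double knr  = kmnai / nai;                 // (kmnai/nai)^1.5
      const double fnk  = 1.0 / (1.0 + knr * std::sqrt(knr));
      const double inak = g.inakmax * LI(cFNAK) * fnk * Ko / (Ko + kmko);
      const double nai3 = nai * nai * nai;
      const double e2   = LI(cNC2);
      const double inaca = g.inacamax * (LI(cNC1) * nai3 * Cao - e2 * Nao * Nao * Nao * cai)
                           / (naca_den0 * (1.0 + ksat * e2));
      const double ibna = g.gbna * (V - c.ena);
      const double ibca = g.gbca * (V - eca);
      const double ipca = g.ipcamax * cai / (0.0005 + cai);

      // ---- Ca release subsystem
      const double irel = krel * s[iU] * s[iU] * s[iVg] * s[iW] * (s[iCAREL] - cai);
      const double Fn = 1e3 * (1e-15 * Vrel_ * irel
                        - 1e-15 / (2.0 * Far) * (0.5 * ical * Cm - 0.4 * inaca * Cm));
      const double s1 = sig_lut((Fn - 3.4175e-13) / 13.67e-16);
      const double uinf = s1;
      const double tauv = 1.91 + 2.09 * s1;
      const double vinf = 1.0 - sig_lut((Fn - 6.835e-14) / 13.67e-16);
      s[iU]  += dt * (uinf - s[iU]) / tauu;
      s[iVg] += dt * (vinf - s[iVg]) / tauv;

      const double iup = iupmax / (1.0 + kup / cai);
      const double iupleak = iupmax * s[iCAUP] / caupmax;
      const double itr = (s[iCAUP] - s[iCAREL]) / tautr;

      // ---- concentration updates (currents in pA: multiply by Cm)
      const double b1 = (2.0 * inaca - (ipca + ical + ibca)) * Cm / (2.0 * Vi_ * Far)
                        + (Vup_ * (iupleak - iup) + irel * Vrel_) / Vi_;
      const double cm2 = cai + kmcmdn, tr2 = cai + kmtrpn;
      const double b2 = 1.0 + trpnmax * kmtrpn / (tr2 * tr2)
                            + cmdnmax * kmcmdn / (cm2 * cm2);
      s[iCAI]  += dt * b1 / b2;
      s[iCAUP] += dt * (iup - iupleak - itr * Vrel_ / Vup_);
      const double cs2 = s[iCAREL] + kmcsqn;
      s[iCAREL] += dt * (itr - irel) / (1.0 + csqnmax * kmcsqn / (cs2 * cs2));
      s[iNAI] += dt * (-3.0 * inak - (3.0 * inaca + ibna + ina)) * Cm / (Vi_ * Far);
      s[iKI]  += dt * (2.0 * inak - (ik1 + ito + ikur + ikr + iks)) * Cm / (Vi_ * Far);

      const double iion = ina + ik1 + ito + ikur + ikr + iks + ical
                        + inak + inaca + ibna + ibca + ipca;
      s[iV] = V + dt * (-iion + (any_stim ? istim[i] : 0.0) + Dc * lap[i]);
#undef LI
    }
    if (step % 40000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix out_state(NSTATE, n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < NSTATE; ++k) out_state(k, i) = S[(size_t)i * NSTATE + k];

  List out = List::create(
    _["state"] = out_state,
    _["t_end"] = t0 + nsteps * dt,
    _["sample_t"] = samp_t,
    _["probe_vm"] = probe_vm,
    _["refractory_pct"] = refr_pct,
    _["ecg"] = ecg,
    _["frame_t"] = frames_t,
    _["frames_vm"] = frames_vm,
    _["frames_h"] = frames_h);
  return out;
}
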