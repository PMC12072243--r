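// Two-compartment conductance-based model of a lateral habenular neuron
// electrically coupled to a lumped non-neuronal (glial) compartment.
//
// Units: mV, ms, nS, pF, pA.  dV/dt = I/C gives mV/ms = pA/pF.
//
// Neuron: leak, Wang-Buzsaki-style Na/K spike currents with slow Na
// inactivation (amplitude adaptation), adaptation K current (frequency
// adaptation), T-type Ca current (rebound trigger), Ca pool + SK current
// (RDP shortening), optional H current (sag).
// Glial compartment: leak, its own T-type conductance (post-junctional
// rebound amplification) and a CNG-like conductance whose slow gate s is
// charged while the glial voltage exceeds theta_CNG and decays with rate
// beta (1/beta of order seconds) -> long-RDP plateau.
//
// Fixed-step 4th-order Runge-Kutta; optional Ornstein-Uhlenbeck current
// noise updated per step (Euler-Maruyama) with an internal deterministic
// RNG so identical seeds give bitwise-identical traces.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// parameter vector layout (kept in step with .paramVector() on the R side)
enum Par {
  P_C_N, P_C_G, P_GL_N, P_EL_N, P_GL_G, P_EL_G,
  P_GNA, P_ENA, P_GK, P_EK,
  P_GT, P_GTG, P_ECA, P_VMT, P_KMT, P_VHT, P_KHT,
  P_TAUH_MIN, P_TAUH_AMP, P_TAUH_VMID, P_TAUH_K,
  P_GSK, P_KCA, P_NHILL, P_KCAIN, P_TAUCA, P_SKCPL,
  P_GAD, P_VAD, P_KAD, P_TAUAD,
  P_TAUNAP, P_VNAP, P_KNAP,
  P_GH, P_EH, P_VR, P_KR, P_TAUR,
  P_VMTG, P_VHTG,
  P_GCNG, P_ECNG, P_ALPHA, P_BETA, P_THETA,
  P_TAUGATE,
  P_GGAP, P_SIGMA, P_TAUOU, P_PHI, P_NASHIFT,
  NPAR
};

// state vector layout (shared with R for steady-state initialisation)
enum St {
  S_VN, S_H, S_N, S_HT, S_CA, S_A, S_P, S_R,
  S_VG, S_HTG, S_S, S_VGS,
  NSTATE
};

static inline double sigm(double v, double vhalf, double k) {
  return 1.0 / (1.0 + std::exp(-(v - vhalf) / k));
}

static inline double minf_na(double v) {
  // Wang-Buzsaki m_inf (instantaneous activation)
  double am, bm;
  double x = v + 35.0;
  if (std::fabs(x) < 1e-6) am = 1.0; else am = 0.1 * x / (1.0 - std::exp(-x / 10.0));
  bm = 4.0 * std::exp(-(v + 60.0) / 18.0);
  return am / (am + bm);
}

struct Deriv {
  const double *p;
  double i_ext;   // injected + holding + noise current into the neuron (pA)
  double i_g;     // independent noise current into the glial compartment (pA)

  void operator()(const double *y, double *dy) const {
    const double vn = y[S_VN], vg = y[S_VG];

    // --- neuron spike currents (Wang-Buzsaki kinetics, phi-accelerated;
    //     na_shift moves the spike threshold down by shifting the rates) ---
    const double vs = vn + p[P_NASHIFT];
    double am_h = 0.07 * std::exp(-(vs + 58.0) / 20.0);
    double bm_h = 1.0 / (1.0 + std::exp(-(vs + 28.0) / 10.0));
    double x = vs + 34.0;
    double am_n = (std::fabs(x) < 1e-6) ? 0.1 : 0.01 * x / (1.0 - std::exp(-x / 10.0));
    double bm_n = 0.125 * std::exp(-(vs + 44.0) / 80.0);
    const double phi = p[P_PHI];
    double m3 = minf_na(vs); m3 = m3 * m3 * m3;
    double i_na = p[P_GNA] * y[S_P] * m3 * y[S_H] * (vn - p[P_ENA]);
    double i_k  = p[P_GK] * std::pow(y[S_N], 4) * (vn - p[P_EK]);

    // --- T-type Ca (neuron) ---
    double mt = sigm(vn, p[P_VMT], p[P_KMT]);
    double i_t = p[P_GT] * mt * mt * y[S_HT] * (vn - p[P_ECA]);
    double ht_inf = 1.0 / (1.0 + std::exp((vn - p[P_VHT]) / p[P_KHT]));
    double tau_ht = p[P_TAUH_MIN] +
      p[P_TAUH_AMP] / (1.0 + std::exp((vn - p[P_TAUH_VMID]) / p[P_TAUH_K]));

    // --- SK (Ca-gated K), Ca pool driven by I_T ---
    double ca_eff = p[P_SKCPL] * y[S_CA];
    double can = std::pow(ca_eff, p[P_NHILL]);
    double sk_open = can / (can + std::pow(p[P_KCA], p[P_NHILL]));
    double i_sk = p[P_GSK] * sk_open * (vn - p[P_EK]);

    // --- adaptation K current, slow Na inactivation ---
    double i_ad = p[P_GAD] * y[S_A] * (vn - p[P_EK]);
    double a_inf = sigm(vn, p[P_VAD], p[P_KAD]);
    double p_inf = 1.0 / (1.0 + std::exp((vn - p[P_VNAP]) / p[P_KNAP]));

    // --- H current (sag) ---
    double i_h = p[P_GH] * y[S_R] * (vn - p[P_EH]);
    double r_inf = 1.0 / (1.0 + std::exp((vn - p[P_VR]) / p[P_KR]));

    // --- gap junction ---
    double i_gap_n = p[P_GGAP] * (vn - vg);   // out of neuron into glia

    dy[S_VN] = (-p[P_GL_N] * (vn - p[P_EL_N]) - i_na - i_k - i_t - i_sk
                - i_ad - i_h - i_gap_n + i_ext) / p[P_C_N];
    dy[S_H]  = phi * (am_h * (1.0 - y[S_H]) - bm_h * y[S_H]);
    dy[S_N]  = phi * (am_n * (1.0 - y[S_N]) - bm_n * y[S_N]);
    dy[S_HT] = (ht_inf - y[S_HT]) / tau_ht;
    dy[S_CA] = -p[P_KCAIN] * i_t - y[S_CA] / p[P_TAUCA];
    dy[S_A]  = (a_inf - y[S_A]) / p[P_TAUAD];
    dy[S_P]  = (p_inf - y[S_P]) / p[P_TAUNAP];
    dy[S_R]  = (r_inf - y[S_R]) / p[P_TAUR];

    // --- glial compartment ---
    double mtg = sigm(vg, p[P_VMTG], p[P_KMT]);
    double i_tg = p[P_GTG] * mtg * mtg * y[S_HTG] * (vg - p[P_ECA]);
    double htg_inf = 1.0 / (1.0 + std::exp((vg - p[P_VHTG]) / p[P_KHT]));
    double tau_htg = p[P_TAUH_MIN] +
      p[P_TAUH_AMP] / (1.0 + std::exp((vg - p[P_TAUH_VMID]) / p[P_TAUH_K]));
    double i_cng = p[P_GCNG] * y[S_S] * (vg - p[P_ECNG]);

    dy[S_VG] = (-p[P_GL_G] * (vg - p[P_EL_G]) - i_tg - i_cng
                + p[P_GGAP] * (vn - vg) + i_g) / p[P_C_G];
    dy[S_HTG] = (htg_inf - y[S_HTG]) / tau_htg;
    // gate drive sensed through a slow (signalling) low-pass of Vg so that
    // transmitted 1-2 ms spikes cannot re-trigger the plateau
    dy[S_VGS] = (vg - y[S_VGS]) / p[P_TAUGATE];
    double gate = (y[S_VGS] > p[P_THETA]) ? 1.0 : 0.0;   // Heaviside drive
    dy[S_S] = p[P_ALPHA] * gate * (1.0 - y[S_S]) - p[P_BETA] * y[S_S];
  }
};

// xorshift64* PRNG + Box-Muller: platform-independent determinism
struct NoiseGen {
  uint64_t state;
  bool has_spare;
  double spare;
  explicit NoiseGen(uint64_t seed) : state(seed ? seed : 0x9E3779B97F4A7C15ULL),
                                     has_spare(false), spare(0.0) {}
  double unif() {
    state ^= state >> 12; state ^= state << 25; state ^= state >> 27;
    uint64_t r = state * 0x2545F4914F6CDD1DULL;
    return ((r >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u = unif(), v = unif();
    double rad = std::sqrt(-2.0 * std::log(u));
    spare = rad * std::sin(2.0 * M_PI * v);
    has_spare = true;
    return rad * std::cos(2.0 * M_PI * v);
  }
};

static inline void clamp01(double &v) { if (v < 0.0) v = 0.0; else if (v > 1.0) v = 1.0; }

static inline void clamp_states(double *y) {
  clamp01(y[S_H]); clamp01(y[S_N]); clamp01(y[S_HT]); clamp01(y[S_A]);
  clamp01(y[S_P]); clamp01(y[S_R]); clamp01(y[S_HTG]); clamp01(y[S_S]);
  if (y[S_CA] < 0.0) y[S_CA] = 0.0;
}

// [[Rcpp::export(name = ".rdp_simulate_cpp")]]
List rdp_simulate_cpp(NumericVector par, NumericVector init,
                      double dt, double settle_ms, double t_total_ms,
                      double t_on_ms, double t_off_ms, double amp_pA,
                      double i_hold, int stride, double seed) {
  if (par.size() != NPAR) stop("internal: parameter vector has wrong length");
  if (init.size() != NSTATE) stop("internal: state vector has wrong length");
  if (dt <= 0) stop("integration step dt must be positive");

  const double *p = REAL(par);
  double y[NSTATE], k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE], tmp[NSTATE];
  for (int i = 0; i < NSTATE; ++i) y[i] = init[i];

  long n_settle = (long)std::lround(settle_ms / dt);
  long n_steps  = (long)std::lround(t_total_ms / dt);
  int n_out = (int)(n_steps / stride) + 1;

  NumericVector vn_out(n_out), vg_out(n_out), i_out(n_out);

  Deriv f; f.p = p;
  double sigma = p[P_SIGMA], tau_ou = p[P_TAUOU];
  bool noisy = sigma > 0.0;
  NoiseGen rng((uint64_t)std::llround(seed));
  NoiseGen rng_g((uint64_t)std::llround(seed) * 0x9E3779B9ULL + 1ULL);
  double i_noise = 0.0, i_noise_g = 0.0;
  double ou_decay = 0.0, ou_diff = 0.0;
  if (noisy) {
    ou_decay = dt / tau_ou;
    ou_diff = sigma * std::sqrt(2.0 * dt / tau_ou);
  }

  int out_idx = 0;
  bool diverged = false;
  double t_div = NA_REAL;

  for (long k = -n_settle; k <= n_steps; ++k) {
    double t = k * dt;   // ms, 0 = recording start
    if (k >= 0 && (k % stride) == 0) {
      double i_inj = (t >= t_on_ms && t < t_off_ms) ? amp_pA : 0.0;
      vn_out[out_idx] = y[S_VN];
      vg_out[out_idx] = y[S_VG];
      i_out[out_idx] = i_inj;
      ++out_idx;
      if (out_idx == n_out && k == n_steps) break;
    }
    if (k == n_steps) break;

    if (noisy) {
      i_noise += -i_noise * ou_decay + ou_diff * rng.norm();
      i_noise_g += -i_noise_g * ou_decay + ou_diff * rng_g.norm();
    }

    // injected current held constant across the RK4 substeps of one dt
    double i_inj = (t >= t_on_ms && t < t_off_ms) ? amp_pA : 0.0;
    f.i_ext = i_inj + i_hold + i_noise;
    f.i_g = i_noise_g;

    f(y, k1);
    for (int i = 0; i < NSTATE; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
    f(tmp, k2);
    for (int i = 0; i < NSTATE; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
    f(tmp, k3);
    for (int i = 0; i < NSTATE; ++i) tmp[i] = y[i] + dt * k3[i];
    f(tmp, k4);
    for (int i = 0; i < NSTATE; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    clamp_states(y);

    if (std::fabs(y[S_VN]) > 200.0 || std::fabs(y[S_VG]) > 200.0 ||
        !std::isfinite(y[S_VN]) || !std::isfinite(y[S_VG])) {
      diverged = true;
      t_div = t;
      break;
    }
  }

  return List::create(_["vn"] = vn_out, _["vg"] = vg_out, _["i"] = i_out,
                      _["diverged"] = diverged, _["t_diverged_ms"] = t_div,
                      _["final_state"] = NumericVector(y, y + NSTATE));
}
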