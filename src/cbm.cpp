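// Conductance-based hypercolumn core: Hodgkin-Huxley-type neurons with
// transient sodium, delayed-rectifier potassium, persistent sodium, A-type
// potassium and slow (adaptation) potassium currents, white-noise input
// current, and double-exponential conductance synapses on a ring.
//
// Integration is a second-order explicit (Heun) scheme; the white-noise
// current is sampled once per step with 1/sqrt(dt) scaling and held for both
// stages. Voltage-dependent gating functions are evaluated through fine
// lookup tables with linear interpolation.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

constexpr double V_TAB_MIN = -130.0;
constexpr double V_TAB_MAX = 60.0;
constexpr double V_TAB_STEP = 0.02;
constexpr int V_TAB_N = static_cast<int>((V_TAB_MAX - V_TAB_MIN) / V_TAB_STEP) + 2;
constexpr double PHI = 5.0;       // temperature factor on h, n kinetics
constexpr double TAU_B = 20.0;    // ms, A-current inactivation
constexpr double TAU_Z = 50.0;    // ms, slow-K activation
constexpr double C_M = 1.0;       // uF/cm^2
constexpr double V_SPIKE = -20.0; // mV, spike detection threshold
constexpr double LOCKOUT = 2.0;   // ms

inline double alpha_m(double v) {
  double x = -0.1 * (v + 35.0);
  return (std::fabs(x) < 1e-8) ? 1.0 : -0.1 * (v + 35.0) / (std::exp(x) - 1.0) * 1.0;
}
inline double beta_m(double v) { return 4.0 * std::exp(-(v + 60.0) / 18.0); }
inline double alpha_h(double v) { return 0.07 * std::exp(-(v + 58.0) / 20.0); }
inline double beta_h(double v) { return 1.0 / (std::exp(-0.1 * (v + 28.0)) + 1.0); }
inline double alpha_n(double v) {
  double x = -0.1 * (v + 38.0);
  return (std::fabs(x) < 1e-8) ? 0.1 : -0.01 * (v + 38.0) / (std::exp(x) - 1.0);
}
inline double beta_n(double v) { return 0.125 * std::exp(-(v + 48.0) / 80.0); }
inline double s_inf_f(double v) { return 1.0 / (1.0 + std::exp(-(v + 40.0) / 4.0)); }
inline double a_inf_f(double v) { return 1.0 / (1.0 + std::exp(-(v + 50.0) / 16.0)); }
inline double b_inf_f(double v) { return 0.1 + 0.55 / (1.0 + std::exp((v + 58.0) / 10.0)); }
inline double z_inf_f(double v) { return 1.0 / (1.0 + std::exp(-0.7 * (v + 30.0))); }

struct GatingTables {
  // 9 functions of voltage, interleaved per grid point:
  // m3, hinf, hk, ninf, nk, sinf, a3, binf, zinf
  std::vector<double> flat;
  GatingTables() {
    flat.resize(9 * V_TAB_N);
    for (int i = 0; i < V_TAB_N; ++i) {
      double v = V_TAB_MIN + i * V_TAB_STEP;
      double am = alpha_m(v), bm = beta_m(v);
      double m = am / (am + bm);
      double ah = alpha_h(v), bh = beta_h(v);
      double an = alpha_n(v), bn = beta_n(v);
      double a = a_inf_f(v);
      double* row = &flat[9 * i];
      row[0] = m * m * m;
      row[1] = ah / (ah + bh);
      row[2] = PHI * (ah + bh);
      row[3] = an / (an + bn);
      row[4] = PHI * (an + bn);
      row[5] = s_inf_f(v);
      row[6] = a * a * a;
      row[7] = b_inf_f(v);
      row[8] = z_inf_f(v);
    }
  }
};

const GatingTables TAB;
constexpr double V_TAB_INV_STEP = 1.0 / V_TAB_STEP;

// Box-Muller normal deviates driven by R's uniform RNG (seed-deterministic,
// cheaper than the default inversion method for the ~1e7 draws per trial).
struct NormalGen {
  bool have = false;
  double cached = 0.0;
  double operator()() {
    if (have) { have = false; return cached; }
    double u1, u2;
    do { u1 = unif_rand(); } while (u1 <= 0.0);
    u2 = unif_rand();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586 * u2;
    cached = r * std::sin(a);
    have = true;
    return r * std::cos(a);
  }
};

// Interpolated row of all 9 gating functions at voltage v.
inline void lut_row(double v, double* out) {
  double x = (v - V_TAB_MIN) * V_TAB_INV_STEP;
  if (x < 0.0) x = 0.0;
  if (x > V_TAB_N - 2) x = V_TAB_N - 2;
  int i = static_cast<int>(x);
  double f = x - i;
  const double* r0 = &TAB.flat[9 * i];
  const double* r1 = r0 + 9;
  for (int k = 0; k < 9; ++k) out[k] = r0[k] + f * (r1[k] - r0[k]);
}

// Single-function lookups used only during initialization.
inline double lut1(int k, double v) {
  double x = (v - V_TAB_MIN) * V_TAB_INV_STEP;
  if (x < 0.0) x = 0.0;
  if (x > V_TAB_N - 2) x = V_TAB_N - 2;
  int i = static_cast<int>(x);
  double f = x - i;
  return TAB.flat[9 * i + k] + f * (TAB.flat[9 * (i + 1) + k] - TAB.flat[9 * i + k]);
}

struct NeuronPars {
  double gL, EL, gNa, ENa, gNaP, gK, EK, gA, gKs;
};

struct NeuronState {
  double V, h, n, b, z;
};

inline void init_at_voltage(NeuronState& st, double v) {
  st.V = v;
  st.h = lut1(1, v);
  st.n = lut1(3, v);
  st.b = lut1(7, v);
  st.z = lut1(8, v);
}

// Membrane + gating derivatives given total non-ionic current I_in
// (external drive + noise + synaptic current evaluated by the caller).
inline void derivs(const NeuronPars& p, const NeuronState& s, double I_in,
                   double extra_gL, double* d) {
  double v = s.V;
  double g[9];
  lut_row(v, g);
  double ik = (v - p.EK);
  double ina = (v - p.ENa);
  double n2 = s.n * s.n;
  double I_ion = (p.gL + extra_gL) * (v - p.EL)
    + p.gNa * g[0] * s.h * ina
    + p.gK * n2 * n2 * ik
    + p.gNaP * g[5] * ina
    + p.gA * g[6] * s.b * ik
    + p.gKs * s.z * ik;
  d[0] = (-I_ion + I_in) / C_M;
  d[1] = g[2] * (g[1] - s.h);
  d[2] = g[4] * (g[3] - s.n);
  d[3] = (g[7] - s.b) / TAU_B;
  d[4] = (g[8] - s.z) / TAU_Z;
}

inline void heun_step(const NeuronPars& p, NeuronState& s, double I0,
                      double I1, double extra_gL, double dt) {
  double d1[5], d2[5];
  derivs(p, s, I0, extra_gL, d1);
  NeuronState pred;
  pred.V = s.V + dt * d1[0];
  pred.h = s.h + dt * d1[1];
  pred.n = s.n + dt * d1[2];
  pred.b = s.b + dt * d1[3];
  pred.z = s.z + dt * d1[4];
  derivs(p, pred, I1, extra_gL, d2);
  s.V += 0.5 * dt * (d1[0] + d2[0]);
  s.h += 0.5 * dt * (d1[1] + d2[1]);
  s.n += 0.5 * dt * (d1[2] + d2[2]);
  s.b += 0.5 * dt * (d1[3] + d2[3]);
  s.z += 0.5 * dt * (d1[4] + d2[4]);
}

NeuronPars pars_from_row(const NumericMatrix& m, int i) {
  NeuronPars p;
  p.gL = m(i, 0); p.EL = m(i, 1); p.gNa = m(i, 2); p.ENa = m(i, 3);
  p.gNaP = m(i, 4); p.gK = m(i, 5); p.EK = m(i, 6); p.gA = m(i, 7);
  p.gKs = m(i, 8);
  return p;
}

} // namespace

// Single conductance-based neuron driven by a constant current plus white
// noise. Returns spike times, window statistics and (optionally) a thinned
// voltage trace.
// [[Rcpp::export]]
List cbm_neuron_run(NumericVector pars, double I_ext, double sigma_noise,
                    double T, double dt, double extra_gL, double t_discard,
                    double clip, int record_stride, double V_init) {
  if (dt > 0.1) stop("Conductance-based integration requires dt <= 0.1 ms.");
  NeuronPars p;
  p.gL = pars[0]; p.EL = pars[1]; p.gNa = pars[2]; p.ENa = pars[3];
  p.gNaP = pars[4]; p.gK = pars[5]; p.EK = pars[6]; p.gA = pars[7];
  p.gKs = pars[8];
  NeuronState st;
  init_at_voltage(st, V_init);

  int n_steps = static_cast<int>(std::ceil(T / dt));
  double inv_sqrt_dt = (sigma_noise > 0.0) ? sigma_noise / std::sqrt(dt) : 0.0;
  std::vector<double> spikes;
  std::vector<double> v_trace, t_trace;
  double last_spike = -1e9;
  double sum_v = 0.0, sum_v2 = 0.0, sum_clip = 0.0;
  long n_win = 0;

  RNGScope scope;
  NormalGen nrm;
  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt;
    double noise = (inv_sqrt_dt > 0.0) ? inv_sqrt_dt * nrm() : 0.0;
    double v_old = st.V;
    double I_in = I_ext + noise;
    heun_step(p, st, I_in, I_in, extra_gL, dt);
    if (!std::isfinite(st.V) || std::fabs(st.V) > 200.0) {
      stop("Conductance-based integration blew up (|V| > 200 mV) at dt = %f ms.", dt);
    }
    double t_new = t + dt;
    if (st.V >= V_SPIKE && v_old < V_SPIKE && (t_new - last_spike) > LOCKOUT) {
      last_spike = t_new;
      spikes.push_back(t_new);
    }
    if (t_new > t_discard) {
      ++n_win;
      sum_v += st.V;
      sum_v2 += st.V * st.V;
      sum_clip += (st.V > clip) ? clip : st.V;
    }
    if (record_stride > 0 && s % record_stride == 0) {
      v_trace.push_back(st.V);
      t_trace.push_back(t_new);
    }
  }
  int n_spk_win = 0;
  for (double ts : spikes) if (ts > t_discard) ++n_spk_win;
  double window = T - t_discard;
  double mean_v = (n_win > 0) ? sum_v / n_win : NA_REAL;
  double var_v = (n_win > 1) ? (sum_v2 / n_win - mean_v * mean_v) : NA_REAL;
  return List::create(
    _["spikes"] = wrap(spikes),
    _["rate"] = (window > 0) ? 1000.0 * n_spk_win / window : NA_REAL,
    _["mean_V"] = mean_v,
    _["sd_V"] = (var_v > 0) ? std::sqrt(var_v) : 0.0,
    _["mean_V_clipped"] = (n_win > 0) ? sum_clip / n_win : NA_REAL,
    _["V"] = wrap(v_trace),
    _["t"] = wrap(t_trace));
}

// Resting state of a neuron: integrate noise-free until the voltage settles.
// [[Rcpp::export]]
double cbm_resting_V(NumericVector pars, double T, double dt) {
  NeuronPars p;
  p.gL = pars[0]; p.EL = pars[1]; p.gNa = pars[2]; p.ENa = pars[3];
  p.gNaP = pars[4]; p.gK = pars[5]; p.EK = pars[6]; p.gA = pars[7];
  p.gKs = pars[8];
  NeuronState st;
  init_at_voltage(st, p.EL);
  int n_steps = static_cast<int>(std::ceil(T / dt));
  for (int s = 0; s < n_steps; ++s) {
    heun_step(p, st, 0.0, 0.0, 0.0, dt);
    if (!std::isfinite(st.V) || std::fabs(st.V) > 200.0)
      stop("Resting-state integration blew up.");
  }
  return st.V;
}

// Full spiking hypercolumn: N neurons (E and I mixed), all-to-all ring
// weights W (column j = outgoing weights of neuron j, in integrated
// conductance units mS/cm^2 per spike), double-exponential synaptic kernels
// maintained as rise/decay accumulator pairs per source population.
// [[Rcpp::export]]
List cbm_network_run(NumericMatrix pars, IntegerVector is_exc, NumericMatrix W,
                     double VrevE, double VrevI, double tau_r, double tau_d,
                     NumericVector I_lgn, double sigma_noise, double T,
                     double dt, double t_discard, double clip,
                     bool return_spikes) {
  if (dt > 0.1) stop("Conductance-based integration requires dt <= 0.1 ms.");
  const int N = pars.nrow();
  if (W.nrow() != N || W.ncol() != N || I_lgn.size() != N || is_exc.size() != N)
    stop("Inconsistent network dimensions.");
  std::vector<NeuronPars> P(N);
  std::vector<NeuronState> S(N);
  for (int i = 0; i < N; ++i) {
    P[i] = pars_from_row(pars, i);
    init_at_voltage(S[i], P[i].EL);
  }
  std::vector<double> DE(N, 0.0), RE(N, 0.0), DI(N, 0.0), RI(N, 0.0);
  const double fd = std::exp(-dt / tau_d), fr = std::exp(-dt / tau_r);
  const double knorm = 1.0 / (tau_d - tau_r);
  const double inv_sqrt_dt = (sigma_noise > 0.0) ? sigma_noise / std::sqrt(dt) : 0.0;

  int n_steps = static_cast<int>(std::ceil(T / dt));
  std::vector<double> last_spike(N, -1e9);
  std::vector<int> spk_count(N, 0);
  std::vector<double> sum_clip(N, 0.0), sum_gE(N, 0.0), sum_gI(N, 0.0);
  std::vector<double> sum_v(N, 0.0), sum_v2(N, 0.0);
  long n_win = 0;
  std::vector<int> raster_id;
  std::vector<double> raster_t;
  std::vector<int> spiked;
  spiked.reserve(64);

  RNGScope scope;
  NormalGen nrm;
  for (int s = 0; s < n_steps; ++s) {
    double t_new = (s + 1) * dt;
    bool in_win = t_new > t_discard;
    if (in_win) ++n_win;
    spiked.clear();
    for (int i = 0; i < N; ++i) {
      double gE0 = (DE[i] - RE[i]) * knorm;
      double gI0 = (DI[i] - RI[i]) * knorm;
      double gE1 = (DE[i] * fd - RE[i] * fr) * knorm;
      double gI1 = (DI[i] * fd - RI[i] * fr) * knorm;
      double noise = (inv_sqrt_dt > 0.0) ? inv_sqrt_dt * nrm() : 0.0;
      double v_old = S[i].V;
      // synaptic currents enter stage-wise through the (time-varying)
      // conductances; voltage dependence handled inside the two stages
      double d1[5], d2[5];
      double I1 = I_lgn[i] + noise - gE0 * (S[i].V - VrevE) - gI0 * (S[i].V - VrevI);
      derivs(P[i], S[i], I1, 0.0, d1);
      NeuronState pred;
      pred.V = S[i].V + dt * d1[0];
      pred.h = S[i].h + dt * d1[1];
      pred.n = S[i].n + dt * d1[2];
      pred.b = S[i].b + dt * d1[3];
      pred.z = S[i].z + dt * d1[4];
      double I2 = I_lgn[i] + noise - gE1 * (pred.V - VrevE) - gI1 * (pred.V - VrevI);
      derivs(P[i], pred, I2, 0.0, d2);
      S[i].V += 0.5 * dt * (d1[0] + d2[0]);
      S[i].h += 0.5 * dt * (d1[1] + d2[1]);
      S[i].n += 0.5 * dt * (d1[2] + d2[2]);
      S[i].b += 0.5 * dt * (d1[3] + d2[3]);
      S[i].z += 0.5 * dt * (d1[4] + d2[4]);
      if (!std::isfinite(S[i].V) || std::fabs(S[i].V) > 200.0)
        stop("Network integration blew up (neuron %d, |V| > 200 mV) at dt = %f ms.",
             i + 1, dt);
      if (S[i].V >= V_SPIKE && v_old < V_SPIKE && (t_new - last_spike[i]) > LOCKOUT) {
        last_spike[i] = t_new;
        spiked.push_back(i);
        if (in_win) ++spk_count[i];
        if (return_spikes) {
          raster_id.push_back(i + 1);
          raster_t.push_back(t_new);
        }
      }
      if (in_win) {
        double v = S[i].V;
        sum_clip[i] += (v > clip) ? clip : v;
        sum_v[i] += v;
        sum_v2[i] += v * v;
        sum_gE[i] += gE1;
        sum_gI[i] += gI1;
      }
    }
    // decay the synaptic accumulators, then add this step's spikes
    for (int i = 0; i < N; ++i) {
      DE[i] *= fd; RE[i] *= fr; DI[i] *= fd; RI[i] *= fr;
    }
    for (int j : spiked) {
      const double* wcol = &W(0, j);
      if (is_exc[j]) {
        for (int i = 0; i < N; ++i) {
          DE[i] += wcol[i];
          RE[i] += wcol[i];
        }
      } else {
        for (int i = 0; i < N; ++i) {
          DI[i] += wcol[i];
          RI[i] += wcol[i];
        }
      }
    }
  }
  double window = T - t_discard;
  NumericVector rate(N), meanV(N), sdV(N), mgE(N), mgI(N);
  for (int i = 0; i < N; ++i) {
    rate[i] = 1000.0 * spk_count[i] / window;
    meanV[i] = sum_clip[i] / n_win;
    double mv = sum_v[i] / n_win;
    double var = sum_v2[i] / n_win - mv * mv;
    sdV[i] = (var > 0) ? std::sqrt(var) : 0.0;
    mgE[i] = sum_gE[i] / n_win;
    mgI[i] = sum_gI[i] / n_win;
  }
  List out = List::create(
    _["rate"] = rate,
    _["mean_V_clipped"] = meanV,
    _["sd_V"] = sdV,
    _["mean_gE"] = mgE,
    _["mean_gI"] = mgI);
  if (return_spikes) {
    out["raster"] = DataFrame::create(_["neuron"] = wrap(raster_id),
                                      _["time_ms"] = wrap(raster_t));
  }
  return out;
}
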