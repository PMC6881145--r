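#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Forward-Euler integration of an exponential integrate-and-fire neuron with
// an I_h activation gate and a D-type K+ current (activation x slow
// inactivation). Units: pF, nS, mV, ms, pA. Membrane noise is diffusive
// (added to dV each step, scaled so the passive stationary sd equals
// noise_sd); it is drawn from R's RNG so set.seed() governs reproducibility.
//
// The voltage-dependent nonlinearities (three gate steady states and the
// spike-initiation exponential) are tabulated on a 0.05 mV grid with linear
// interpolation; the grid error is far below the integration error of the
// Euler scheme at dt = 0.025 ms.

static inline double gate_inf(double v, double vhalf, double k) {
  return 1.0 / (1.0 + std::exp((vhalf - v) / k));
}

namespace {

struct Model {
  double Cm, gL, EL, VT, DeltaT, Vreset, t_ref, Vcut;
  double gh, Eh, h_vhalf, h_k, h_tau;
  double gD, EK, Da_vhalf, Da_k, Da_tau, Di_vhalf, Di_k, Di_tau;
  double noise_sd;

  // lookup tables over [v_lo, v_hi]
  static constexpr double v_lo = -160.0, v_hi = 40.0, dv = 0.05;
  std::vector<double> t_h, t_a, t_d, t_e;

  explicit Model(List p) {
    Cm = p["Cm"]; gL = p["gL"]; EL = p["EL"];
    VT = p["VT"]; DeltaT = p["DeltaT"];
    Vreset = p["Vreset"]; t_ref = p["t_ref"]; Vcut = p["Vcut"];
    gh = p["gh_max"]; Eh = p["Eh"];
    h_vhalf = p["h_vhalf"]; h_k = p["h_k"]; h_tau = p["h_tau"];
    gD = p["gD_max"]; EK = p["EK"];
    Da_vhalf = p["Da_vhalf"]; Da_k = p["Da_k"]; Da_tau = p["Da_tau"];
    Di_vhalf = p["Di_vhalf"]; Di_k = p["Di_k"]; Di_tau = p["Di_tau"];
    noise_sd = p["noise_sd"];

    const int n = (int)((v_hi - v_lo) / dv) + 2;
    t_h.resize(n); t_a.resize(n); t_d.resize(n); t_e.resize(n);
    for (int i = 0; i < n; ++i) {
      double v = v_lo + i * dv;
      t_h[i] = gate_inf(v, h_vhalf, h_k);
      t_a[i] = gate_inf(v, Da_vhalf, Da_k);
      t_d[i] = gate_inf(v, Di_vhalf, Di_k);
      double ex = (v - VT) / DeltaT;
      t_e[i] = std::exp(ex > 20.0 ? 20.0 : ex);
    }
  }

  inline void lookup(double v, double &h, double &a, double &d, double &e) const {
    double u = (v - v_lo) * (1.0 / dv);
    if (u < 0.0) u = 0.0;
    const double umax = (double)(t_h.size() - 2);
    if (u > umax) u = umax;
    int i = (int)u;
    double w = u - i;
    h = t_h[i] + w * (t_h[i + 1] - t_h[i]);
    a = t_a[i] + w * (t_a[i + 1] - t_a[i]);
    d = t_d[i] + w * (t_d[i + 1] - t_d[i]);
    e = t_e[i] + w * (t_e[i + 1] - t_e[i]);
  }
};

// integrate one sweep; `I` is the command current (relative to holding).
// Noise is injected every `noise_every` steps (0.2 ms at the default dt)
// with variance scaled accordingly; the membrane low-pass (tau ~ 10 ms)
// makes this indistinguishable from per-step injection while keeping the
// RNG off the hot path.
void integrate(const Model &m, const double *I, int n, double dt,
               double v0, double h0, double a0, double d0,
               double I_hold, bool with_noise,
               double *v_out, std::vector<int> &spikes, double *state_out) {
  const double tau_m = m.Cm / m.gL;
  const int noise_every = std::max(1, (int)std::floor(0.2 / dt));
  const double noise_fac =
      (with_noise && m.noise_sd > 0)
          ? m.noise_sd * std::sqrt(2.0 * dt * noise_every / tau_m)
          : 0.0;
  const int ref_steps = (int)std::ceil(m.t_ref / dt);
  const double r_h = dt / m.h_tau, r_a = dt / m.Da_tau, r_d = dt / m.Di_tau;
  const double inv_Cm = 1.0 / m.Cm, gLDT = m.gL * m.DeltaT;
  double V = v0, h = h0, a = a0, d = d0;
  double hi, ai, di, ei;
  int ref = 0, noise_ctr = 0;

  for (int t = 0; t < n; ++t) {
    m.lookup(V, hi, ai, di, ei);
    h += r_h * (hi - h);
    a += r_a * (ai - a);
    d += r_d * (di - d);

    if (ref > 0) {
      --ref;
      V = m.Vreset;
    } else {
      double ionic = -m.gL * (V - m.EL) + gLDT * ei
                     - m.gh * h * (V - m.Eh) - m.gD * a * d * (V - m.EK);
      V += dt * (ionic + I[t] + I_hold) * inv_Cm;
      if (noise_fac > 0.0 && ++noise_ctr >= noise_every) {
        noise_ctr = 0;
        V += noise_fac * norm_rand();
      }
      if (V >= m.Vcut) {
        V = m.Vcut; // explicit spike peak sample
        v_out[t] = V;
        spikes.push_back(t + 1);
        V = m.Vreset;
        ref = ref_steps;
        continue;
      }
      if (V > 250.0 || V < -250.0) {
        stop("simulation failure: voltage diverged beyond +/-250 mV at step %d",
             t + 1);
      }
    }
    v_out[t] = V;
  }
  state_out[0] = V; state_out[1] = h; state_out[2] = a; state_out[3] = d;
}

} // namespace

// [[Rcpp::export]]
List eif_simulate_cpp(NumericVector I, List params, double dt,
                      double v0, double h0, double a0, double d0,
                      double I_hold, bool with_noise) {
  Model m(params);
  const int n = I.size();
  NumericVector v(n);
  std::vector<int> spikes;
  double state[4];
  RNGScope scope;
  integrate(m, REAL(I), n, dt, v0, h0, a0, d0, I_hold, with_noise,
            REAL(v), spikes, state);
  return List::create(_["v"] = v,
                      _["spike_idx"] = IntegerVector(spikes.begin(), spikes.end()),
                      _["state"] = NumericVector::create(state[0], state[1],
                                                         state[2], state[3]));
}

// Batched current-step sweeps sharing one model: each sweep is a rectangular
// step of amps[k] between samples n_pre+1 .. n_pre+n_step (1-based), padded
// by n_pre baseline and n_post tail samples. Sweeps start from the holding
// steady state and are independent (the inter-sweep interval in the recording
// protocol far exceeds all model time constants).
// `sweep_bias` is a per-sweep standing-current offset (pA) emulating slow
// brain-state fluctuations of excitability between trials.
// [[Rcpp::export]]
List eif_step_block_cpp(List params, double dt, int n_pre, int n_step,
                        int n_post, NumericVector amps,
                        double v0, double h0, double a0, double d0,
                        double I_hold, bool with_noise,
                        NumericVector sweep_bias) {
  Model m(params);
  const int n = n_pre + n_step + n_post;
  const int ns = amps.size();
  NumericMatrix v(n, ns);
  List spike_list(ns);
  std::vector<double> I(n);
  double state[4];
  RNGScope scope;
  for (int k = 0; k < ns; ++k) {
    std::fill(I.begin(), I.end(), 0.0);
    std::fill(I.begin() + n_pre, I.begin() + n_pre + n_step, amps[k]);
    std::vector<int> spikes;
    double bias = sweep_bias.size() == ns ? sweep_bias[k] : 0.0;
    integrate(m, I.data(), n, dt, v0, h0, a0, d0, I_hold + bias, with_noise,
              &v(0, k), spikes, state);
    spike_list[k] = IntegerVector(spikes.begin(), spikes.end());
  }
  return List::create(_["v"] = v, _["spikes"] = spike_list);
}
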