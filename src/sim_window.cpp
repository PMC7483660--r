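#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Core presentation-window integrator for a three-layer network with
// reciprocal hidden-output connectivity.
//
// Input neurons are clamped analog currents (symbolic percepts, possibly
// with working-memory superposition). Hidden neurons are conductance-based
// LIF units with threshold reset and refractory period. Output neurons
// integrate without reset so the decision variable is the time-averaged
// (normalised) membrane potential and the decision time is the first
// threshold crossing.
//
// Per step, each non-input neuron blends the feed-forward potential change
// with a homeostatic correction (weight `1 - blend` on the correction), the
// homeostatic imbalance being v_i - (sum_j w_ji a_j - theta) in normalised
// potential units.
//
// Hidden drive combines the static input projection with feedback from the
// output layer through the same synapses (`fb` scales the feedback); during
// training a teaching signal can clamp the output potentials (normalised
// units), so the teaching-induced displacement of the hidden potentials is
// observable and can be consolidated into weights.
//
// The activity average reported for plasticity is a rate-potential code:
// the time-averaged normalised potential plus `spike_boost_ms` of
// threshold-level activity per emitted spike (the reset sawtooth alone
// compresses rate information).

struct LifPrm {
  double tau_m, tau_e, g_l, v_l, v_e, v_th, t0, eta, dt, span;
};

struct WinResult {
  std::vector<double> act_h, act_o, vh_final, vo_final, de_h, de_o, cross;
  std::vector<int> spk_h, spk_o;
};

static LifPrm read_prm(List prm) {
  LifPrm p;
  p.tau_m = prm["tau_m"]; p.tau_e = prm["tau_e"]; p.g_l = prm["g_l"];
  p.v_l = prm["v_l"]; p.v_e = prm["v_e"]; p.v_th = prm["v_th"];
  p.t0 = prm["t_ref"]; p.eta = prm["eta"]; p.dt = prm["dt"];
  p.span = p.v_th - p.v_l;
  if (p.span <= 0) stop("invalid potentials: need v_l < v_th");
  return p;
}

static void run_window(const double* w1, const double* w2, int n_in,
                       int n_hid, int n_out, const double* input,
                       const LifPrm& p, int n_steps, double blend,
                       double eta_i, double theta, double spike_boost_ms,
                       double fb, const double* clamp, WinResult& r) {
  std::vector<double> vh(n_hid, p.v_l), gh(n_hid, 0.0), refh(n_hid, 0.0);
  std::vector<double> vo(n_out, p.v_l), go(n_out, 0.0), von(n_out, 0.0);
  std::vector<double> vhn(n_hid, 0.0), impulse(n_out, 0.0),
      static_h(n_hid, 0.0);
  std::vector<bool> above(n_out, false);
  r.act_h.assign(n_hid, 0.0); r.act_o.assign(n_out, 0.0);
  r.de_h.assign(n_hid, 0.0); r.de_o.assign(n_out, 0.0);
  r.spk_h.assign(n_hid, 0); r.spk_o.assign(n_out, 0);
  r.cross.assign(n_out, NA_REAL);

  for (int h = 0; h < n_hid; ++h) {
    double d = 0.0;
    for (int j = 0; j < n_in; ++j) d += w1[j + h * n_in] * input[j];
    static_h[h] = d;
  }
  if (clamp) {
    for (int o = 0; o < n_out; ++o) {
      von[o] = clamp[o];
      vo[o] = p.v_l + clamp[o] * p.span;
    }
  }

  for (int s = 0; s < n_steps; ++s) {
    std::fill(impulse.begin(), impulse.end(), 0.0);
    // hidden layer: static input drive plus output feedback
    for (int h = 0; h < n_hid; ++h) {
      double d = static_h[h];
      for (int o = 0; o < n_out; ++o) d += fb * w2[h + o * n_hid] * von[o];
      gh[h] += p.dt / p.tau_e * (-gh[h] + p.eta * d);
      if (gh[h] < 0) gh[h] = 0;
      double v_norm = (vh[h] - p.v_l) / p.span;
      double de = v_norm - (d - theta);
      r.de_h[h] += de;
      if (refh[h] > 0) {
        refh[h] -= p.dt;
        vh[h] = p.v_l;
      } else {
        double dv_ff = p.dt / p.tau_m *
            (-(vh[h] - p.v_l) - gh[h] / p.g_l * (vh[h] - p.v_e));
        double corr = -eta_i * de * p.span * p.dt / p.tau_m;
        vh[h] += dv_ff + (1.0 - blend) * corr;
        if (vh[h] > p.v_th) {
          r.spk_h[h] += 1;
          vh[h] = p.v_l;
          refh[h] = p.t0;
          r.act_h[h] += spike_boost_ms / p.dt;
          for (int o = 0; o < n_out; ++o)
            impulse[o] += p.eta * w2[h + o * n_hid];
        }
      }
      // rectified at rest: a hyperpolarised membrane transmits nothing
      vhn[h] = (vh[h] - p.v_l) / p.span;
      if (vhn[h] < 0) vhn[h] = 0;
      r.act_h[h] += vhn[h];
    }
    // output layer: integrates freely unless teacher-clamped
    for (int o = 0; o < n_out; ++o) {
      double d = 0.0;
      for (int h = 0; h < n_hid; ++h) d += w2[h + o * n_hid] * vhn[h];
      double v_norm = (vo[o] - p.v_l) / p.span;
      r.de_o[o] += v_norm - (d - theta);
      if (!clamp) {
        go[o] += p.dt / p.tau_e * (-go[o] + p.eta * d) + impulse[o];
        if (go[o] < 0) go[o] = 0;
        double dv_ff = p.dt / p.tau_m *
            (-(vo[o] - p.v_l) - go[o] / p.g_l * (vo[o] - p.v_e));
        double corr = -eta_i * (v_norm - (d - theta)) * p.span * p.dt /
            p.tau_m;
        vo[o] += dv_ff + (1.0 - blend) * corr;
        bool ab = vo[o] > p.v_th;
        if (ab && !above[o]) {
          r.spk_o[o] += 1;
          if (ISNA(r.cross[o])) r.cross[o] = (s + 1) * p.dt;
        }
        above[o] = ab;
        von[o] = (vo[o] - p.v_l) / p.span;
        if (von[o] < 0) von[o] = 0;
      }
      r.act_o[o] += von[o];
    }
  }
  for (int h = 0; h < n_hid; ++h) {
    r.act_h[h] /= n_steps;
    r.de_h[h] /= n_steps;
  }
  for (int o = 0; o < n_out; ++o) {
    r.act_o[o] /= n_steps;
    r.de_o[o] /= n_steps;
  }
  r.vh_final = vh;
  r.vo_final = vo;
}

static void check_finite(NumericMatrix w1, NumericMatrix w2,
                         const double* input, int n_in) {
  for (int j = 0; j < n_in; ++j)
    if (!R_finite(input[j])) stop("non-finite input current");
  for (int i = 0; i < w1.size(); ++i)
    if (!R_finite(w1[i])) stop("non-finite synaptic weight");
  for (int i = 0; i < w2.size(); ++i)
    if (!R_finite(w2[i])) stop("non-finite synaptic weight");
}

// [[Rcpp::export]]
List sim_window_cpp(NumericMatrix w1, NumericMatrix w2, NumericVector input,
                    List prm, int n_steps, double blend, double eta_i,
                    double theta, double spike_boost_ms = 10.0,
                    double fb = 0.3,
                    Nullable<NumericVector> clamp_out = R_NilValue) {
  const int n_in = w1.nrow(), n_hid = w1.ncol(), n_out = w2.ncol();
  if (w2.nrow() != n_hid) stop("weight matrix shapes disagree");
  if (input.size() != n_in) stop("input length does not match input layer");
  if (n_steps < 1) stop("window shorter than one time step");
  check_finite(w1, w2, input.begin(), n_in);
  LifPrm p = read_prm(prm);
  NumericVector vclamp;
  const double* clamp_ptr = nullptr;
  if (clamp_out.isNotNull()) {
    vclamp = clamp_out.get();
    if (vclamp.size() != n_out) stop("teacher clamp length mismatch");
    clamp_ptr = vclamp.begin();
  }
  WinResult r;
  run_window(w1.begin(), w2.begin(), n_in, n_hid, n_out, input.begin(), p,
             n_steps, blend, eta_i, theta, spike_boost_ms, fb, clamp_ptr, r);
  return List::create(
      _["act_hidden"] = wrap(r.act_h), _["act_output"] = wrap(r.act_o),
      _["v_hidden_final"] = wrap(r.vh_final),
      _["v_output_final"] = wrap(r.vo_final),
      _["spikes_hidden"] = wrap(r.spk_h), _["spikes_output"] = wrap(r.spk_o),
      _["imbalance_hidden"] = wrap(r.de_h),
      _["imbalance_output"] = wrap(r.de_o),
      _["decision_ms"] = wrap(r.cross));
}

// One full training epoch of the four-step scheme: for each sample (in the
// given order) a free presentation, a teacher-clamped presentation, the
// Eq-(7)-style teacher displacement of the outputs, and STDP consolidation
// of the displacements into both weight matrices, with bounds. Weights are
// modified in the copies and returned.
// [[Rcpp::export]]
List train_epoch_cpp(NumericMatrix w1, NumericMatrix w2, NumericMatrix x,
                     IntegerVector targets, IntegerVector order, List prm,
                     int n_steps, double t_glob, double t_total,
                     double eta_i, double theta, double spike_boost_ms,
                     double fb, double eta_c, double kappa, double v_t_hi,
                     double w1_max, double w2_max, double decay = 0.0) {
  const int n_in = w1.nrow(), n_hid = w1.ncol(), n_out = w2.ncol();
  const int n = x.nrow();
  if (x.ncol() != n_in) stop("sample matrix width does not match inputs");
  if (targets.size() != n || order.size() != n) {
    stop("targets/order length mismatch");
  }
  LifPrm p = read_prm(prm);
  NumericMatrix w1c = clone(w1), w2c = clone(w2);
  std::vector<double> input(n_in), vt(n_out);
  WinResult free_r, clamp_r;
  double loss = 0, imb_h = 0, imb_o = 0;
  for (int idx = 0; idx < n; ++idx) {
    int k = order[idx] - 1;
    if (k < 0 || k >= n) stop("order index out of range");
    int tgt = targets[k] - 1;
    if (tgt < 0 || tgt >= n_out) stop("target outside the output layer");
    for (int j = 0; j < n_in; ++j) input[j] = x(k, j);
    double b = t_glob / t_total;
    if (b > 1) b = 1;
    run_window(w1c.begin(), w2c.begin(), n_in, n_hid, n_out, input.data(),
               p, n_steps, b, eta_i, theta, spike_boost_ms, fb, nullptr,
               free_r);
    for (int o = 0; o < n_out; ++o) vt[o] = (o == tgt) ? v_t_hi : 0.0;
    run_window(w1c.begin(), w2c.begin(), n_in, n_hid, n_out, input.data(),
               p, n_steps, b, eta_i, theta, spike_boost_ms, fb, vt.data(),
               clamp_r);
    // readout: presynaptic activity times the teacher displacement
    for (int o = 0; o < n_out; ++o) {
      double dv = -eta_c * (free_r.act_o[o] - vt[o]);
      loss += (free_r.act_o[o] - vt[o]) * (free_r.act_o[o] - vt[o]) / n_out;
      for (int h = 0; h < n_hid; ++h) {
        double w = w2c[h + o * n_hid] + kappa * free_r.act_h[h] * dv;
        if (w > w2_max) w = w2_max;
        if (w < -w2_max) w = -w2_max;
        w2c[h + o * n_hid] = w;
      }
    }
    // hidden: input currents times the teaching-induced displacement, with
    // slow multiplicative decay pruning synapses the task never recruits
    for (int h = 0; h < n_hid; ++h) {
      double dv = eta_c * (clamp_r.act_h[h] - free_r.act_h[h]);
      imb_h += std::abs(free_r.de_h[h]) / n_hid;
      for (int j = 0; j < n_in; ++j) {
        double w = (1.0 - decay) * w1c[j + h * n_in] +
            kappa * input[j] * dv;
        if (w > w1_max) w = w1_max;
        if (w < 0) w = 0;
        w1c[j + h * n_in] = w;
      }
    }
    for (int o = 0; o < n_out; ++o) imb_o += std::abs(free_r.de_o[o]) / n_out;
    t_glob += 1.0;
  }
  return List::create(_["w1"] = w1c, _["w2"] = w2c, _["loss"] = loss / n,
                      _["imbalance_hidden"] = imb_h / n,
                      _["imbalance_output"] = imb_o / n,
                      _["t_glob"] = t_glob);
}

// Batch inference: time-averaged output potentials for each row of x under
// pure feed-forward dynamics.
// [[Rcpp::export]]
NumericMatrix infer_batch_cpp(NumericMatrix w1, NumericMatrix w2,
                              NumericMatrix x, List prm, int n_steps,
                              double theta, double spike_boost_ms,
                              double fb) {
  const int n_in = w1.nrow(), n_hid = w1.ncol(), n_out = w2.ncol();
  const int n = x.nrow();
  LifPrm p = read_prm(prm);
  NumericMatrix out(n, n_out);
  std::vector<double> input(n_in);
  WinResult r;
  for (int k = 0; k < n; ++k) {
    for (int j = 0; j < n_in; ++j) input[j] = x(k, j);
    run_window(w1.begin(), w2.begin(), n_in, n_hid, n_out, input.data(), p,
               n_steps, 1.0, 0.0, theta, spike_boost_ms, fb, nullptr, r);
    for (int o = 0; o < n_out; ++o) out(k, o) = r.act_o[o];
  }
  return out;
}
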