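#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Event kinds delivered through the queue.
enum EvKind { EV_A_TO_B1 = 0, EV_A_TO_B2 = 1, EV_INH = 2, EV_PLASTIC = 3 };

struct Ev {
  int kind;
  int ch;   // target channel (0-based); -1 = all channels (global inhibition)
  int syn;  // plastic synapse index, -1 otherwise
};

// Fixed-step simulation of the tonotopic A/B1/B2 network.
//
// Update order inside one step mirrors the (time, population A<B1<B2,
// channel) tie-break: A neurons integrate first and their spikes are queued
// for strictly later steps; events due this step are then delivered as
// potential kicks; B1 integrates (and queues its lateral events); B2
// integrates last, so a postsynaptic spike simultaneous with a presynaptic
// arrival does not count as "post before pre" for the calcium gate.
//
// Plastic efficacies use lazy bistable drift: each synapse stores the step
// at which it was last brought up to date; drift is applied in closed form
// (piecewise-linear, no threshold crossing possible between events) when the
// synapse is next touched and once more at the end of the run.
// [[Rcpp::export]]
List sim_core(NumericMatrix drive, bool use_drive,
              IntegerVector a_spike_step, IntegerVector a_spike_ch,
              int n_steps, List np, List netp, List pp,
              IntegerVector syn_x, IntegerVector syn_y,
              IntegerVector syn_delay_steps, NumericVector syn_w0,
              bool learning, bool record_a, bool record_deliveries) {
  const int n = as<int>(netp["n_channels"]);
  const double dt = as<double>(netp["dt"]);
  const double w_a_b1 = as<double>(netp["w_a_b1"]);
  const double w_a_b2 = as<double>(netp["w_a_b2"]);
  const double w_inh = as<double>(netp["w_inh"]);
  const double w_pl_max = as<double>(netp["w_plastic_max"]);
  const double d0 = as<double>(netp["d0"]);
  std::string inh_mode = as<std::string>(netp["inhibition_mode"]);
  const int inh = inh_mode == "off" ? 0 : (inh_mode == "same" ? 1 : 2);

  const double tau_m = as<double>(np["tau_m"]);
  const double v_rest = as<double>(np["v_rest"]);
  const double v_thresh = as<double>(np["v_thresh"]);
  const double v_reset = as<double>(np["v_reset"]);
  const double r_in = as<double>(np["r_in"]);
  const int n_refr = (int) std::lround(as<double>(np["t_refr"]) / dt);

  const double w_theta = as<double>(pp["w_theta"]);
  const double alpha_up = as<double>(pp["alpha_up"]);
  const double beta_down = as<double>(pp["beta_down"]);
  const double a_pot = as<double>(pp["a_pot"]);
  const double b_dep = as<double>(pp["b_dep"]);
  const double ca_pot = as<double>(pp["ca_thresh_pot"]);
  const double ca_dep = as<double>(pp["ca_thresh_dep"]);
  const double tau_ca = as<double>(pp["tau_ca"]);
  const double ca_jump = as<double>(pp["ca_jump"]);

  const int nsyn = syn_x.size();
  int d0_steps = (int) std::lround(d0 / dt);
  if (d0_steps < 1) d0_steps = 1;

  // per-B1 outgoing plastic synapse lists
  std::vector<std::vector<int>> out_syn(n);
  int max_delay = d0_steps;
  for (int s = 0; s < nsyn; ++s) {
    out_syn[syn_x[s] - 1].push_back(s);
    if (syn_delay_steps[s] > max_delay) max_delay = syn_delay_steps[s];
  }
  const int ring_n = max_delay + 2;
  std::vector<std::vector<Ev>> ring(ring_n);

  std::vector<double> vA(n, v_rest), vB1(n, v_rest), vB2(n, v_rest);
  std::vector<int> rA(n, 0), rB1(n, 0), rB2(n, 0);
  std::vector<double> kickB1(n, 0.0), kickB2(n, 0.0);
  std::vector<double> ca(n, 0.0);
  std::vector<int> ca_step(n, 0);
  std::vector<double> w(syn_w0.begin(), syn_w0.end());
  std::vector<int> w_step(nsyn, 0);

  std::vector<double> ev_time; std::vector<int> ev_pop, ev_ch;
  std::vector<double> del_time; std::vector<int> del_x, del_y;

  const double leak = dt / tau_m;
  int a_idx = 0;
  const int n_a_spk = a_spike_step.size();

  auto drift_to = [&](int s, int step) {
    double el = (step - w_step[s]) * dt;
    if (el > 0) {
      if (w[s] > w_theta) w[s] = std::min(1.0, w[s] + alpha_up * el);
      else w[s] = std::max(0.0, w[s] - beta_down * el);
      w_step[s] = step;
    }
  };
  auto ca_at = [&](int c, int step) {
    if (step > ca_step[c]) {
      ca[c] *= std::exp(-(step - ca_step[c]) * dt / tau_ca);
      ca_step[c] = step;
    }
    return ca[c];
  };

  for (int step = 0; step < n_steps; ++step) {
    const double t_spk = (step + 1) * dt;

    // --- A population ---
    if (use_drive) {
      for (int c = 0; c < n; ++c) {
        if (rA[c] > 0) { --rA[c]; vA[c] = v_reset; continue; }
        double v = vA[c] + leak * ((v_rest - vA[c]) + r_in * drive(c, step));
        if (v >= v_thresh) {
          v = v_reset; rA[c] = n_refr;
          if (record_a) { ev_time.push_back(t_spk); ev_pop.push_back(0); ev_ch.push_back(c + 1); }
          ring[(step + d0_steps) % ring_n].push_back({EV_A_TO_B1, c, -1});
          ring[(step + d0_steps) % ring_n].push_back({EV_A_TO_B2, c, -1});
        }
        vA[c] = v;
      }
    } else {
      while (a_idx < n_a_spk && a_spike_step[a_idx] == step) {
        int c = a_spike_ch[a_idx] - 1;
        if (record_a) { ev_time.push_back(t_spk); ev_pop.push_back(0); ev_ch.push_back(c + 1); }
        ring[(step + d0_steps) % ring_n].push_back({EV_A_TO_B1, c, -1});
        ring[(step + d0_steps) % ring_n].push_back({EV_A_TO_B2, c, -1});
        ++a_idx;
      }
    }

    // --- deliver events due this step ---
    std::vector<Ev> &due = ring[step % ring_n];
    for (size_t i = 0; i < due.size(); ++i) {
      const Ev &e = due[i];
      switch (e.kind) {
      case EV_A_TO_B1: kickB1[e.ch] += w_a_b1; break;
      case EV_A_TO_B2: kickB2[e.ch] += w_a_b2; break;
      case EV_INH:
        if (e.ch >= 0) kickB2[e.ch] -= w_inh;
        else for (int c = 0; c < n; ++c) kickB2[c] -= w_inh;
        break;
      case EV_PLASTIC: {
        int s = e.syn;
        int y = syn_y[s] - 1;
        double w_transmit;
        if (learning) {
          drift_to(s, step);
          w_transmit = w[s];
          double c_now = ca_at(y, step);
          if (c_now >= ca_pot) w[s] = std::min(1.0, w[s] + a_pot);
          else if (c_now >= ca_dep) w[s] = std::max(0.0, w[s] - b_dep);
        } else {
          w_transmit = w[s];
        }
        kickB2[y] += w_transmit * w_pl_max;
        if (record_deliveries) {
          del_time.push_back(t_spk);
          del_x.push_back(syn_x[s]); del_y.push_back(syn_y[s]);
        }
        break;
      }
      }
    }
    due.clear();

    // --- B1 population ---
    for (int c = 0; c < n; ++c) {
      double k = kickB1[c]; kickB1[c] = 0.0;
      if (rB1[c] > 0) { --rB1[c]; vB1[c] = v_reset; continue; }
      double v = vB1[c] + leak * (v_rest - vB1[c]) + k;
      if (v >= v_thresh) {
        v = v_reset; rB1[c] = n_refr;
        ev_time.push_back(t_spk); ev_pop.push_back(1); ev_ch.push_back(c + 1);
        if (inh == 1)
          ring[(step + d0_steps) % ring_n].push_back({EV_INH, c, -1});
        else if (inh == 2)
          ring[(step + d0_steps) % ring_n].push_back({EV_INH, -1, -1});
        for (size_t j = 0; j < out_syn[c].size(); ++j) {
          int s = out_syn[c][j];
          ring[(step + syn_delay_steps[s]) % ring_n].push_back({EV_PLASTIC, -1, s});
        }
      }
      vB1[c] = v;
    }

    // --- B2 population ---
    for (int c = 0; c < n; ++c) {
      double k = kickB2[c]; kickB2[c] = 0.0;
      if (rB2[c] > 0) { --rB2[c]; vB2[c] = v_reset; continue; }
      double v = vB2[c] + leak * (v_rest - vB2[c]) + k;
      if (v >= v_thresh) {
        v = v_reset; rB2[c] = n_refr;
        ev_time.push_back(t_spk); ev_pop.push_back(2); ev_ch.push_back(c + 1);
        double c_now = ca_at(c, step);
        ca[c] = c_now + ca_jump;
      }
      vB2[c] = v;
    }
  }

  if (learning)
    for (int s = 0; s < nsyn; ++s) drift_to(s, n_steps);

  return List::create(
    _["time_ms"] = wrap(ev_time), _["pop"] = wrap(ev_pop),
    _["channel"] = wrap(ev_ch), _["w_final"] = wrap(w),
    _["del_time"] = wrap(del_time), _["del_x"] = wrap(del_x),
    _["del_y"] = wrap(del_y));
}
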