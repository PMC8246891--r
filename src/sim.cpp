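// Clock-driven leaky integrate-and-fire network engine with voltage-drive
// alpha-function post-synaptic potentials.
//
// Per neuron and receptor type, the alpha kernel is integrated exactly as a
// pair of first-order states (y1, y2) sharing the synaptic time constant:
//   y1' = -y1/tau,  y2' = -y2/tau + y1
// An incoming spike with delivery amplitude a increments y1 by a*e/tau so
// that an isolated spike produces a PSP a*(t/tau)*exp(1 - t/tau) with peak
// a at t = tau.  Delivery amplitudes fold the synapse weight (attenuation
// times redundancy), the receptor amplitude, the receptor sign (GABA_A
// negative) and any receptor-block gain.  The membrane follows
//   tau_m V' = -V + Vin,  Vin = V_C + sum_r y2_r
// advanced by the exact exponential propagator with Vin held constant over
// one step.  The membrane is clamped at reset during refractoriness while
// kernel states keep evolving.  All randomness comes from R's RNG.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".sim_engine")]]
List sim_engine(int n_neurons,
                IntegerVector nucleus_id,     // per neuron, 0-based
                NumericVector tau_m,          // per nucleus (ms)
                NumericVector theta,          // per nucleus (mV)
                NumericVector v_c,            // per nucleus (mV)
                NumericVector t_ref,          // per nucleus (ms)
                IntegerVector syn_offset,     // CSR over pre id, len n_pre+1
                IntegerVector syn_post,
                IntegerVector syn_delay,      // steps
                NumericVector amp_ampa,       // delivery amplitudes per syn
                NumericVector amp_nmda,
                NumericVector amp_gaba,
                int n_sources,
                NumericMatrix source_rates,   // n_segments x n_sources (Hz)
                NumericVector seg_start,      // ms, first must be 0
                IntegerVector ext_pre,        // explicit spikes: pre ids
                IntegerVector ext_step,       // sorted ascending
                NumericVector tau_syn,        // AMPA, NMDA, GABAA (ms)
                double dt,
                double duration,
                IntegerVector trace_ids,      // record V for these neurons
                bool record_sources) {
  const int n_steps = (int)std::llround(duration / dt);
  const int n_rec = 3;
  const int n_nuc = tau_m.size();

  std::vector<double> V(n_neurons, 0.0), refr(n_neurons, -1.0);
  std::vector<double> y1(n_neurons * n_rec, 0.0), y2(n_neurons * n_rec, 0.0);

  // exact per-step decay factors
  std::vector<double> Esyn(n_rec), bump(n_rec);
  for (int r = 0; r < n_rec; ++r) {
    Esyn[r] = std::exp(-dt / tau_syn[r]);
    bump[r] = std::exp(1.0) / tau_syn[r];  // y1 increment per unit amplitude
  }
  std::vector<double> Em(n_nuc);
  for (int k = 0; k < n_nuc; ++k) Em[k] = std::exp(-dt / tau_m[k]);

  // delay ring buffer of pending y1 increments
  int max_delay = 1;
  for (int j = 0; j < syn_delay.size(); ++j)
    if (syn_delay[j] > max_delay) max_delay = syn_delay[j];
  const int L = max_delay + 1;
  std::vector<std::vector<double>> ring(
      L, std::vector<double>(n_neurons * n_rec, 0.0));

  std::vector<int> spike_id;
  std::vector<double> spike_t;
  spike_id.reserve(1 << 16);
  spike_t.reserve(1 << 16);

  const int n_trace = trace_ids.size();
  NumericMatrix trace(n_trace > 0 ? n_steps : 0, n_trace);

  const int n_seg = seg_start.size();
  int seg = 0;

  int ext_i = 0;
  const int n_ext = ext_pre.size();

  auto deliver = [&](int pre, int step) {
    const int from = syn_offset[pre], to = syn_offset[pre + 1];
    for (int j = from; j < to; ++j) {
      const int slot = (step + syn_delay[j]) % L;
      double* tgt = &ring[slot][syn_post[j] * n_rec];
      if (amp_ampa[j] != 0.0) tgt[0] += amp_ampa[j] * bump[0];
      if (amp_nmda[j] != 0.0) tgt[1] += amp_nmda[j] * bump[1];
      if (amp_gaba[j] != 0.0) tgt[2] += amp_gaba[j] * bump[2];
    }
  };

  for (int step = 0; step < n_steps; ++step) {
    const double t_now = (step + 1) * dt;
    while (seg + 1 < n_seg && seg_start[seg + 1] <= step * dt + 1e-9) ++seg;

    // 1. apply increments scheduled for this step, then advance kernels
    std::vector<double>& slot = ring[step % L];
    for (int i = 0; i < n_neurons; ++i) {
      double* yy1 = &y1[i * n_rec];
      double* yy2 = &y2[i * n_rec];
      double* ss = &slot[i * n_rec];
      for (int r = 0; r < n_rec; ++r) {
        const double a = yy1[r] + ss[r];
        ss[r] = 0.0;
        yy2[r] = Esyn[r] * (yy2[r] + dt * a);
        yy1[r] = Esyn[r] * a;
      }
    }

    // 2. membrane update, threshold, spike propagation
    for (int i = 0; i < n_neurons; ++i) {
      const int k = nucleus_id[i];
      if (t_now < refr[i]) { V[i] = 0.0; continue; }
      double vin = v_c[k] + y2[i * n_rec] + y2[i * n_rec + 1] +
                   y2[i * n_rec + 2];
      if (vin > 1e6) vin = 1e6;
      if (vin < -1e6) vin = -1e6;
      V[i] = vin + (V[i] - vin) * Em[k];
      if (V[i] >= theta[k]) {
        spike_id.push_back(i);
        spike_t.push_back(t_now);
        V[i] = 0.0;
        refr[i] = t_now + t_ref[k];
        deliver(i, step);
      }
    }

    // 3. Poisson afferent sources
    if (n_sources > 0) {
      const double* rates = &source_rates(seg, 0);
      // NumericMatrix is column-major: index (seg, s) = s * n_seg + seg
      for (int s = 0; s < n_sources; ++s) {
        const double p = source_rates(seg, s) * dt * 1e-3;
        if (p > 0.0 && unif_rand() < p) {
          deliver(n_neurons + s, step);
          if (record_sources) {
            spike_id.push_back(n_neurons + s);
            spike_t.push_back(t_now);
          }
        }
      }
      (void)rates;
    }

    // 4. explicit (scripted) presynaptic spikes
    while (ext_i < n_ext && ext_step[ext_i] == step) {
      deliver(ext_pre[ext_i], step);
      ++ext_i;
    }

    for (int q = 0; q < n_trace; ++q) trace(step, q) = V[trace_ids[q]];
  }

  return List::create(_["id"] = wrap(spike_id), _["time"] = wrap(spike_t),
                      _["trace"] = trace);
}
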