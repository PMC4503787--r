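#include <Rcpp.h>
using namespace Rcpp;

// Leaky integrate-and-fire network integration.
//
// Per step of length dt:
//   1. summed synaptic drives decay: hE *= exp(-dt/tauE), hI *= exp(-dt/tauI)
//   2. spikes of the previous step increment the drives (one-step delay):
//      presynaptic neuron j adds column W[, j] to hE or hI
//   3. membrane update by exponential Euler treating the drive as constant
//      within the step: V <- Vinf + (V - Vinf) * exp(-dt/tau_m),
//      Vinf = mu + tau_m * (hE + hI)
//   4. V >= threshold emits a spike at the end-of-step time, resets V and
//      clamps the neuron for refr_steps steps.
//
// No RNG here: mu and v0 are drawn on the R side, so the loop is
// deterministic.
//
// [[Rcpp::export]]
List lif_core(const NumericMatrix& W, const LogicalVector& inhib,
              const NumericVector& mu, const NumericVector& v0,
              const NumericVector& tau_m, double dt, int n_steps,
              double tau_e, double tau_i, int refr_steps,
              double threshold, double reset) {
  const int N = W.nrow();
  if (W.ncol() != N) stop("W must be square");
  std::vector<double> V(v0.begin(), v0.end());
  std::vector<double> hE(N, 0.0), hI(N, 0.0);
  std::vector<int> refr(N, 0);
  std::vector<double> em(N), leak_gain(N);
  for (int i = 0; i < N; ++i) {
    em[i] = std::exp(-dt / tau_m[i]);
    leak_gain[i] = tau_m[i];
  }
  const double dE = std::exp(-dt / tau_e);
  const double dI = std::exp(-dt / tau_i);

  std::vector<int> prev_spikes, cur_spikes;
  std::vector<int> spike_id;
  std::vector<double> spike_t;
  spike_id.reserve(1 << 16);
  spike_t.reserve(1 << 16);

  for (int step = 0; step < n_steps; ++step) {
    for (int i = 0; i < N; ++i) { hE[i] *= dE; hI[i] *= dI; }
    for (size_t s = 0; s < prev_spikes.size(); ++s) {
      const int j = prev_spikes[s];
      const double* col = &W(0, j);
      if (inhib[j]) {
        for (int i = 0; i < N; ++i) hI[i] += col[i];
      } else {
        for (int i = 0; i < N; ++i) hE[i] += col[i];
      }
    }
    cur_spikes.clear();
    const double t_spike = (step + 1) * dt;
    for (int i = 0; i < N; ++i) {
      if (refr[i] > 0) { --refr[i]; V[i] = reset; continue; }
      const double vinf = mu[i] + leak_gain[i] * (hE[i] + hI[i]);
      double v = vinf + (V[i] - vinf) * em[i];
      if (!std::isfinite(v))
        stop("membrane potential diverged at t = %f ms (neuron %d); "
             "check the weight matrix scaling", t_spike, i + 1);
      if (v >= threshold) {
        spike_id.push_back(i + 1);
        spike_t.push_back(t_spike);
        cur_spikes.push_back(i);
        v = reset;
        refr[i] = refr_steps;
      }
      V[i] = v;
    }
    std::swap(prev_spikes, cur_spikes);
  }
  return List::create(_["id"] = wrap(spike_id), _["time_ms"] = wrap(spike_t),
                      _["V_end"] = wrap(V));
}
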