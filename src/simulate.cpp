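#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Frozen-weight network simulation loop. Neuron dynamics follow the
// two-variable quadratic integrate model (v' = 0.04 v^2 + 5 v + 140 - u + I,
// u' = a (b v - u)) advanced by semi-implicit Euler substeps: v first, then
// u from the updated v, with threshold detection (v >= v_peak) at every
// substep. Spikes are recorded on the 1 ms grid, at most once per neuron and
// step. Synaptic charge is delivered through a ring buffer at
// t_spike + delay and acts as input current during that step.
//
// Aborts (aborted = true) when the mean per-neuron rate exceeds 500 Hz over
// a full 1 s block, which guards against runaway/overflow-like pathologies.
// [[Rcpp::export]]
List simulate_core(int n_neurons, IntegerVector ptr, IntegerVector targ,
                   IntegerVector delay, NumericVector weight,
                   NumericVector a, NumericVector b, NumericVector c_reset,
                   NumericVector d_reset, IntegerVector input_neuron,
                   double input_amp, int n_steps, int substeps,
                   double v_peak, double v_init) {
  std::vector<double> v(n_neurons, v_init), u(n_neurons);
  for (int i = 0; i < n_neurons; ++i) u[i] = b[i] * v_init;

  int d_max = 1;
  for (int k = 0; k < delay.size(); ++k)
    if (delay[k] > d_max) d_max = delay[k];
  const int n_slots = d_max + 1;
  std::vector<double> buf((size_t)n_slots * n_neurons, 0.0);
  std::vector<double> I(n_neurons, 0.0);

  std::vector<int> spike_neuron;
  std::vector<double> spike_time;
  spike_neuron.reserve(1 << 16);
  spike_time.reserve(1 << 16);
  std::vector<int> last_spike(n_neurons, -1);

  const double h = 1.0 / substeps;
  long block_spikes = 0;
  const long block_limit = 500L * n_neurons;  // 500 Hz per neuron over 1 s
  bool aborted = false;
  int abort_step = -1;

  for (int t = 0; t < n_steps && !aborted; ++t) {
    const int slot = t % n_slots;
    double *bslot = &buf[(size_t)slot * n_neurons];
    for (int i = 0; i < n_neurons; ++i) {
      I[i] = bslot[i];
      bslot[i] = 0.0;
    }
    I[input_neuron[t]] += input_amp;

    for (int s = 0; s < substeps; ++s) {
      for (int i = 0; i < n_neurons; ++i) {
        double vi = v[i];
        vi += h * (0.04 * vi * vi + 5.0 * vi + 140.0 - u[i] + I[i]);
        double ui = u[i] + h * a[i] * (b[i] * vi - u[i]);
        if (vi >= v_peak) {
          // record once per ms; repeated crossings within the same step
          // only reset the state again
          if (last_spike[i] != t) {
            last_spike[i] = t;
            spike_neuron.push_back(i);
            spike_time.push_back((double)t);
            ++block_spikes;
            for (int k = ptr[i]; k < ptr[i + 1]; ++k) {
              const int dslot = (t + delay[k]) % n_slots;
              buf[(size_t)dslot * n_neurons + targ[k]] += weight[k];
            }
          }
          vi = c_reset[i];
          ui += d_reset[i];
        }
        if (!R_finite(vi) || !R_finite(ui))
          stop("non-finite neuron state at step %d (neuron %d)", t, i);
        v[i] = vi;
        u[i] = ui;
      }
    }

    if ((t + 1) % 1000 == 0) {
      if (block_spikes > block_limit) {
        aborted = true;
        abort_step = t;
      }
      block_spikes = 0;
    }
  }

  return List::create(
      _["neurons"] = wrap(spike_neuron), _["times"] = wrap(spike_time),
      _["aborted"] = aborted, _["abort_step"] = abort_step,
      _["abort_rate"] = aborted ? (double)block_limit / n_neurons : 0.0);
}
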