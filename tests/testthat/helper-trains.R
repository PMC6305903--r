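# synthetic spike-train generators used across tests (caller seeds the RNG)

poisson_train <- function(id, rate_hz, duration_ms, t_start = 0) {
  times <- t_start
  rate_ms <- rate_hz / 1000
  repeat {
    nxt <- times[length(times)] + rexp(1, rate_ms)
    if (nxt > t_start + duration_ms) break
    times <- c(times, nxt)
  }
  spike_train(id, times[-1L], t_start, t_start + duration_ms)
}

# faster block-sampling variant for long/high-rate trains
poisson_train_fast <- function(id, rate_hz, duration_ms, t_start = 0) {
  rate_ms <- rate_hz / 1000
  n_guess <- ceiling(rate_ms * duration_ms + 6 * sqrt(rate_ms * duration_ms)) + 10
  isis <- rexp(n_guess, rate_ms)
  times <- cumsum(isis)
  while (times[length(times)] < duration_ms) {
    isis <- rexp(n_guess, rate_ms)
    times <- c(times, times[length(times)] + cumsum(isis))
  }
  spike_train(id, t_start + times[times < duration_ms], t_start,
              t_start + duration_ms)
}

gamma_train <- function(id, shape_k, rate_hz, duration_ms, t_start = 0) {
  # gamma renewal process with mean ISI 1000/rate_hz ms and order shape_k
  rate_ms <- rate_hz / 1000
  n_guess <- ceiling(rate_ms * duration_ms * 1.5) + 20
  times <- cumsum(rgamma(n_guess, shape = shape_k, rate = shape_k * rate_ms))
  while (times[length(times)] < duration_ms) {
    more <- cumsum(rgamma(n_guess, shape = shape_k, rate = shape_k * rate_ms))
    times <- c(times, times[length(times)] + more)
  }
  spike_train(id, t_start + times[times < duration_ms], t_start,
              t_start + duration_ms)
}

# pair of trains sharing spikes copied from a common mother train with
# probability c (single-interaction/common-mother thinning); each child has
# total rate rate_hz and pairwise count correlation ~ c in small bins
correlated_pair <- function(rate_hz, c_coupling, duration_ms) {
  mother <- poisson_train_fast(0, rate_hz, duration_ms)
  shared <- mother$spike_times[runif(length(mother$spike_times)) < c_coupling]
  mk <- function(id) {
    own <- poisson_train_fast(id, rate_hz * (1 - c_coupling), duration_ms)
    spike_train(id, sort(unique(c(shared, own$spike_times))), 0, duration_ms)
  }
  list(mk(0), mk(1))
}

regular_train <- function(id, period_ms, duration_ms, offset = 0) {
  spike_train(id, seq(offset, duration_ms - 1e-9, by = period_ms),
              0, duration_ms)
}

small_simulated_set <- function(n_neurons = 100, duration_s = 2, seed = 11) {
  net <- build_network(n_neurons = n_neurons, out_degree = min(50, n_neurons / 2),
                       seed = seed)
  simulate_network(net, duration_s = duration_s, seed = seed + 1)$spikes
}
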