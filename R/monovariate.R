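#' Distribution of a measure across units or pairs
#'
#' Container for the per-neuron or per-pair sample distribution of one
#' statistic. Units for which the measure is undefined (e.g. too few spikes
#' for the local coefficient of variation) are excluded from `values` and
#' counted in `n_excluded` rather than silently set to zero.
#'
#' @param name Measure label, one of `FR`, `LV`, `ISI`, `CC`, `RC`, `P`,
#'   `lambda`.
#' @param values Numeric vector of defined values.
#' @param n_excluded Number of excluded (undefined) units or pairs.
#' @return An object of class `measure_distribution`.
#' @export
measure_distribution <- function(name, values, n_excluded = 0L) {
  stopifnot(is.character(name), length(name) == 1L)
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("measure_distribution values must be finite; exclude undefined entries")
  }
  n_excluded <- as.integer(n_excluded)
  stopifnot(n_excluded >= 0L)
  structure(list(name = name, values = values, n_excluded = n_excluded),
            class = "measure_distribution")
}

#' @export
print.measure_distribution <- function(x, ...) {
  cat(sprintf("measure_distribution %s: n = %d (excluded %d), mean = %.4g, sd = %.4g\n",
              x$name, length(x$values), x$n_excluded,
              mean(x$values), stats::sd(x$values)))
  invisible(x)
}

#' Mean firing rate of a spike train
#'
#' `FR = n_sp / T` with the observation length `T` in seconds; an empty
#' train has rate 0.
#'
#' @param train A [spike_train()].
#' @return Firing rate in Hz.
#' @export
firing_rate <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  length(train$spike_times) / ((train$t_stop - train$t_start) / 1000)
}

#' Inter-spike intervals of a spike train
#'
#' `ISI_i = t_{i+1} - t_i` over the ordered spike times. Trains with fewer
#' than two spikes yield an empty vector.
#'
#' @param train A [spike_train()].
#' @return Numeric vector of intervals in ms (possibly empty).
#' @export
inter_spike_intervals <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  if (length(train$spike_times) < 2L) return(numeric(0))
  diff(train$spike_times)
}

#' Local coefficient of variation of inter-spike intervals
#'
#' Mean over consecutive interval pairs of
#' `3 (I_i - I_{i+1})^2 / (I_i + I_{i+1})^2`. The measure is 1 in
#' expectation for a Poisson process and 0 for perfectly regular firing;
#' for a gamma renewal process of order k its expectation is 3/(2k+1).
#'
#' @param isis Numeric vector of inter-spike intervals (ms), e.g. from
#'   [inter_spike_intervals()].
#' @return The LV value, or `NA_real_` when fewer than two intervals are
#'   available (the unit should then be excluded and counted).
#' @export
local_coefficient_of_variation <- function(isis) {
  isis <- as.numeric(isis)
  n <- length(isis)
  if (n < 2L) return(NA_real_)
  if (any(isis <= 0)) stop("inter-spike intervals must be positive")
  i1 <- isis[-n]; i2 <- isis[-1L]
  mean(3 * (i1 - i2)^2 / (i1 + i2)^2)
}

#' Per-neuron distribution of a monovariate measure
#'
#' @param set A [spike_train_set()].
#' @param measure `"FR"` (per-neuron firing rates, Hz), `"LV"` (per-neuron
#'   local coefficient of variation; units with fewer than 3 spikes are
#'   excluded), or `"ISI"` (inter-spike intervals pooled over neurons, ms;
#'   units with fewer than 2 spikes are excluded).
#' @return A [measure_distribution()].
#' @export
monovariate_distribution <- function(set, measure = c("FR", "LV", "ISI")) {
  stopifnot(inherits(set, "spike_train_set"))
  measure <- match.arg(measure)
  switch(measure,
    FR = measure_distribution("FR",
           vapply(set$trains, firing_rate, numeric(1)), 0L),
    LV = {
      lv <- vapply(set$trains, function(tr) {
        local_coefficient_of_variation(inter_spike_intervals(tr))
      }, numeric(1))
      measure_distribution("LV", lv[!is.na(lv)], sum(is.na(lv)))
    },
    ISI = {
      isis <- lapply(set$trains, inter_spike_intervals)
      empty <- vapply(isis, length, integer(1)) == 0L
      measure_distribution("ISI", unlist(isis[!empty]), sum(empty))
    })
}

#' Population spike-count histogram
#'
#' Spike counts summed over all neurons in equal-width time bins (the
#' column sums of [bin_spike_trains()]).
#'
#' @param set A [spike_train_set()].
#' @param bin_width_ms Bin width in ms (60 ms gives the conventional
#'   population-activity display).
#' @return A list with `counts` (integer vector), `bin_width` and `t_start`.
#' @export
population_rate_histogram <- function(set, bin_width_ms = 60) {
  bm <- bin_spike_trains(set, bin_width_ms)
  list(counts = colSums(bm$counts), bin_width = bm$bin_width,
       t_start = bm$t_start)
}

#' Welch power spectrum of the population activity
#'
#' The population spike count is binned at `1000 / sampling_hz` ms
#' (default 10 ms, i.e. a 100 Hz sampling frequency), split into segments
#' of `sampling_hz / resolution_hz` samples (default 100, i.e. 1 Hz
#' frequency resolution) with 50% overlap; each segment is mean-removed,
#' Hann-tapered and periodogram-averaged.
#'
#' @param set A [spike_train_set()].
#' @param sampling_hz Sampling frequency in Hz.
#' @param resolution_hz Frequency resolution in Hz.
#' @param overlap Segment overlap fraction.
#' @return A list with `frequency` (Hz, 0 to Nyquist) and `power`.
#' @export
welch_population_spectrum <- function(set, sampling_hz = 100,
                                      resolution_hz = 1, overlap = 0.5) {
  stopifnot(inherits(set, "spike_train_set"))
  if ((set$t_stop - set$t_start) < 2000) {
    stop("observation window must be at least 2 s for a Welch spectrum")
  }
  x <- population_rate_histogram(set, 1000 / sampling_hz)$counts
  welch_spectrum(x, sampling_hz, round(sampling_hz / resolution_hz), overlap)
}

# Welch periodogram average of a regularly sampled series (internal core;
# also the path used on precomputed population counts in tests).
welch_spectrum <- function(x, fs, nperseg, overlap = 0.5) {
  n <- length(x)
  if (n < nperseg) stop("series shorter than one Welch segment")
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, nperseg - 1) / nperseg)  # Hann
  scale <- fs * sum(win^2)
  n_freq <- floor(nperseg / 2) + 1L
  acc <- numeric(n_freq)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * win
    p <- Mod(stats::fft(seg)[seq_len(n_freq)])^2 / scale
    # one-sided density: double all but DC and (for even nperseg) Nyquist
    dbl <- seq_len(n_freq) > 1L
    if (nperseg %% 2 == 0) dbl[n_freq] <- FALSE
    p[dbl] <- 2 * p[dbl]
    acc <- acc + p
  }
  list(frequency = (seq_len(n_freq) - 1L) * fs / nperseg,
       power = acc / length(starts))
}
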