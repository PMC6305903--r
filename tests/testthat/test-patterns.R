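# fixture: neurons firing an exact lagged sequence over a silent background
sequence_set <- function(n_repeats, start_times, period = NULL, n_neurons = 5,
                         lag_ms = 3, duration = 1000, extra = list()) {
  if (is.null(start_times)) start_times <- seq(10, by = 200,
                                               length.out = n_repeats)
  trains <- lapply(seq_len(n_neurons) - 1L, function(j) {
    spike_train(j, start_times + j * lag_ms, 0, duration)
  })
  for (tr in extra) trains[[length(trains) + 1L]] <- tr
  spike_train_set(trains, 0, duration)
}

test_that("an exactly repeating 5-spike sequence is found once with all occurrences", {
  set <- sequence_set(4, c(10, 210, 410, 610))
  pats <- mine_patterns(set, mining_config())
  expect_length(pats, 1L)
  expect_equal(pats[[1L]]$size, 5L)
  expect_length(pats[[1L]]$occurrences, 4L)
  expect_equal(unname(pats[[1L]]$neuron_lags[, "lag"]), 0:4)
  expect_equal(unname(pats[[1L]]$neuron_lags[, "neuron"]), 0:4)
  expect_equal(min(pats[[1L]]$neuron_lags[, "lag"]), 0L)
  # only 2 repetitions: below min_occurrences
  expect_length(mine_patterns(sequence_set(2, c(10, 210))), 0L)
  expect_equal(count_patterns(sequence_set(2, c(10, 210))), 0L)
  # silent data
  silent <- spike_train_set(lapply(0:4, function(j)
    spike_train(j, numeric(0), 0, 1000)), 0, 1000)
  expect_length(mine_patterns(silent), 0L)
})

test_that("the span limit is strict and long sequences match the oracle", {
  # 5 spikes spanning 72 ms (lag step 18 ms) exceed the 60 ms limit
  cfg <- mining_config()
  long_seq <- sequence_set(4, c(10, 210, 410, 610), lag_ms = 18)
  pats <- mine_patterns(long_seq, cfg)
  expect_true(all(vapply(pats, function(p) p$size < 5L, logical(1))) ||
              length(pats) == 0L)
  expect_equal(pattern_keys(pats, 5L, 0:4),
               pattern_keys(oracle_patterns(long_seq, cfg), 5L, 0:4))
  # a span of exactly 60 ms is excluded, 57 ms is kept (strict limit)
  mk <- function(lag_bins) {
    trains <- lapply(seq_along(lag_bins), function(j) {
      spike_train(j - 1L, c(10, 210, 410) + lag_bins[j] * 3, 0, 1000)
    })
    spike_train_set(trains, 0, 1000)
  }
  expect_length(mine_patterns(mk(c(0, 5, 10, 15, 19)), cfg), 1L)  # 57 ms
  expect_length(mine_patterns(mk(c(0, 5, 10, 15, 20)), cfg), 0L)  # 60 ms
})

test_that("miner agrees with exhaustive closed-itemset enumeration on random data", {
  set.seed(206)
  for (rep in 1:4) {
    n_neurons <- sample(4:8, 1)
    duration <- 150 * 3
    trains <- lapply(seq_len(n_neurons) - 1L, function(j) {
      poisson_train_fast(j, runif(1, 15, 40), duration)
    })
    set <- spike_train_set(trains, 0, duration)
    cfg <- mining_config(bin_width = 3, min_occurrences = sample(2:3, 1),
                         min_size = sample(2:3, 1), max_span = 24)
    got <- pattern_keys(mine_patterns(set, cfg), n_neurons,
                        seq_len(n_neurons) - 1L)
    want <- pattern_keys(oracle_patterns(set, cfg), n_neurons,
                         seq_len(n_neurons) - 1L)
    expect_setequal(got, want)
  }
})

test_that("patterns are translation invariant and counts are monotone in support", {
  set.seed(99)
  trains <- lapply(0:7, function(j) poisson_train_fast(j, 40, 600))
  set <- spike_train_set(trains, 0, 600)
  cfg <- mining_config(min_occurrences = 2, min_size = 3, max_span = 30)
  base <- mine_patterns(set, cfg)
  shifted <- spike_train_set(lapply(set$trains, function(tr) {
    spike_train(tr$neuron_id, tr$spike_times + 30, 0, 630)
  }), 0, 630)
  shift_pats <- mine_patterns(shifted, cfg)
  expect_equal(lapply(base, `[[`, "neuron_lags"),
               lapply(shift_pats, `[[`, "neuron_lags"))
  expect_equal(lapply(base, function(p) p$occurrences + 10L),
               lapply(shift_pats, `[[`, "occurrences"))
  # loosening min_occurrences never decreases the count
  for (occ in 4:2) {
    expect_gte(count_patterns(set, mining_config(min_occurrences = occ,
                                                 min_size = 3, max_span = 30)),
               count_patterns(set, mining_config(min_occurrences = occ + 1,
                                                 min_size = 3, max_span = 30)))
  }
})

test_that("lag distribution pools pairwise lags normalized to one", {
  p3 <- structure(list(
    neuron_lags = cbind(neuron = 0:2, lag = c(0L, 3L, 6L)),
    occurrences = c(0L, 50L, 90L), size = 3L, span_bins = 6L, bin_width = 3),
    class = "pattern")
  h <- lag_distribution(list(p3))
  expect_equal(h[["9"]], 2 / 3)
  expect_equal(h[["18"]], 1 / 3)
  p2 <- structure(list(
    neuron_lags = cbind(neuron = 0:1, lag = c(0L, 4L)),
    occurrences = c(0L, 10L, 20L), size = 2L, span_bins = 4L, bin_width = 3),
    class = "pattern")
  expect_equal(lag_distribution(list(p2)), c(`12` = 1))
  expect_equal(sum(lag_distribution(list(p3, p2))), 1)
  expect_length(lag_distribution(list()), 0L)
})

test_that("maximal-only reporting filters sub-patterns but closed is the default", {
  # embedded sequence: neurons 0..5 fire a 6-sequence 3 times, and neurons
  # 0..4 additionally fire the 5-prefix alone 2 more times -> the 5-prefix
  # is closed (distinct occurrence set) and reported by default
  starts6 <- c(10, 210, 410)
  starts5 <- c(610, 810)
  trains <- lapply(0:5, function(j) {
    tt <- starts6 + j * 3
    if (j < 5) tt <- c(tt, starts5 + j * 3)
    spike_train(j, sort(tt), 0, 1000)
  })
  set <- spike_train_set(trains, 0, 1000)
  # three closed patterns: the 6-sequence (3 occ.), the 5-prefix (5 occ.,
  # its own occurrence set), and the lag-anchored 5-suffix (3 occ.; its
  # items differ from the 6-sequence because lags are re-anchored at 0)
  closed <- mine_patterns(set, mining_config())
  expect_length(closed, 3L)
  expect_equal(vapply(closed, `[[`, integer(1), "size"), c(6L, 5L, 5L))
  prefix_key <- paste(0:4, 0:4, collapse = " ")
  keys <- vapply(closed, function(p)
    paste(p$neuron_lags[, "neuron"], p$neuron_lags[, "lag"], collapse = " "),
    character(1))
  expect_true(prefix_key %in% keys)
  # the maximal filter drops the prefix (an item subset of the 6-sequence)
  # but keeps the re-anchored suffix, whose items are not a subset
  maximal <- mine_patterns(set, mining_config(maximal = TRUE))
  expect_length(maximal, 2L)
  mkeys <- vapply(maximal, function(p)
    paste(p$neuron_lags[, "neuron"], p$neuron_lags[, "lag"], collapse = " "),
    character(1))
  expect_false(prefix_key %in% mkeys)
  expect_equal(sort(vapply(maximal, `[[`, integer(1), "size")), c(5L, 6L))
})

test_that("mining completes on a dense simulated population (smoke)", {
  set <- small_simulated_set(n_neurons = 200, duration_s = 5, seed = 20)
  pats <- mine_patterns(subset_population(set, "excitatory"))
  expect_true(is.list(pats))
  expect_true(all(vapply(pats, function(p) {
    p$size >= 5L && length(p$occurrences) >= 3L &&
      p$span_bins * p$bin_width < 60 && min(p$neuron_lags[, "lag"]) == 0L
  }, logical(1))))
})
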