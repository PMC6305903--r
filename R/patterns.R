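#' Mining configuration for spatiotemporal spike patterns
#'
#' Defaults follow the conventional settings for this analysis: spike times
#' discretized by 3 ms bins, and only sequences that repeat 3 or more
#' times, are formed by at least 5 spikes, and whose temporal length
#' between first and last spike is (strictly) shorter than 60 ms.
#'
#' @param bin_width Bin width in ms.
#' @param min_occurrences Minimum number of repetitions of a sequence.
#' @param min_size Minimum number of spikes forming a sequence.
#' @param max_span Upper limit (exclusive) on the first-to-last-spike span
#'   in ms.
#' @param maximal If `TRUE`, report only patterns whose item set is not a
#'   subset of another reported pattern (off by default; the default is
#'   closed-itemset semantics).
#' @return An object of class `mining_config`.
#' @export
mining_config <- function(bin_width = 3, min_occurrences = 3L, min_size = 5L,
                          max_span = 60, maximal = FALSE) {
  stopifnot(bin_width > 0, min_occurrences >= 1, min_size >= 1, max_span > 0)
  structure(list(bin_width = as.numeric(bin_width),
                 min_occurrences = as.integer(min_occurrences),
                 min_size = as.integer(min_size),
                 max_span = as.numeric(max_span),
                 maximal = isTRUE(maximal)),
            class = "mining_config")
}

#' Detect repeated spatiotemporal spike patterns
#'
#' Frequent-itemset search for repeated spike sequences in parallel spike
#' trains (the detection stage of spatiotemporal pattern analysis; no
#' significance filtering is applied). Spike trains are binned at
#' `config$bin_width` and binarized (a bin with one or more spikes is one
#' event). A pattern is a set of `(neuron, lag)` items, lags in bins with
#' minimum lag 0; it occurs at window start `w` when every item neuron has
#' an event in bin `w + lag`. Reported patterns are the *closed* frequent
#' itemsets (no superset shares the identical occurrence set) meeting the
#' configured thresholds, in deterministic order: size descending, then
#' occurrence count descending, then lexicographic on the `(neuron, lag)`
#' pairs.
#'
#' @param set A [spike_train_set()].
#' @param config A [mining_config()].
#' @return A list of `pattern` objects, each with `neuron_lags` (two-column
#'   matrix: neuron id, lag in bins), `occurrences` (0-based window start
#'   bins), `size`, `span_bins` and the `bin_width`.
#' @export
mine_patterns <- function(set, config = mining_config()) {
  stopifnot(inherits(set, "spike_train_set"), inherits(config, "mining_config"))
  if (!length(set$trains)) return(list())
  w <- config$bin_width
  span <- set$t_stop - set$t_start
  if (w >= span) return(list())
  n_bins <- floor(span / w)
  # allowed lags are 0 .. n_lags - 1, each with lag * bin_width < max_span
  # (the span limit is strict)
  n_lags <- 1L
  while (n_lags * w < config$max_span) n_lags <- n_lags + 1L
  ids <- neuron_ids(set)
  spike_bins <- lapply(set$trains, function(tr) {
    if (!length(tr$spike_times)) return(integer(0))
    b <- unique(floor((tr$spike_times - set$t_start) / w))
    as.integer(b[b < n_bins])
  })
  res <- mine_patterns_core(spike_bins, as.integer(n_bins), n_lags,
                            config$min_occurrences, config$min_size)
  n_neurons <- length(ids)
  patterns <- mapply(function(items, tids) {
    lag <- items %/% n_neurons
    neuron <- ids[items %% n_neurons + 1L]
    ord <- order(neuron, lag)
    structure(list(neuron_lags = cbind(neuron = neuron[ord], lag = lag[ord]),
                   occurrences = sort(tids),
                   size = length(items),
                   span_bins = max(lag),
                   bin_width = w),
              class = "pattern")
  }, res$items, res$tids, SIMPLIFY = FALSE)
  if (config$maximal && length(patterns) > 1L) {
    keys <- lapply(patterns, function(p) {
      p$neuron_lags[, "neuron"] * 10000L + p$neuron_lags[, "lag"]
    })
    keep <- vapply(seq_along(keys), function(i) {
      !any(vapply(seq_along(keys), function(j) {
        j != i && length(keys[[j]]) > length(keys[[i]]) &&
          all(keys[[i]] %in% keys[[j]])
      }, logical(1)))
    }, logical(1))
    patterns <- patterns[keep]
  }
  # deterministic order: size desc, occurrences desc, lexicographic items
  if (length(patterns) > 1L) {
    key <- vapply(patterns, function(p) {
      paste(sprintf("%06d.%03d", p$neuron_lags[, "neuron"],
                    p$neuron_lags[, "lag"]), collapse = " ")
    }, character(1))
    ord <- order(-vapply(patterns, `[[`, integer(1), "size"),
                 -lengths(lapply(patterns, `[[`, "occurrences")),
                 key)
    patterns <- patterns[ord]
  }
  patterns
}

#' @export
print.pattern <- function(x, ...) {
  cat(sprintf("pattern: %d spikes, span %d bins (%g ms), %d occurrences\n",
              x$size, x$span_bins, x$span_bins * x$bin_width,
              length(x$occurrences)))
  invisible(x)
}

#' Number of detected patterns
#'
#' @inheritParams mine_patterns
#' @return Integer count of patterns returned by [mine_patterns()].
#' @export
count_patterns <- function(set, config = mining_config()) {
  length(mine_patterns(set, config))
}

#' Pooled distribution of within-pattern spike lags
#'
#' Histogram of the absolute temporal lags `|l_i - l_j| * bin_width`
#' between any two spikes involved in one of the patterns, pooled over all
#' patterns and normalized to sum 1.
#'
#' @param patterns A pattern list from one [mine_patterns()] run.
#' @return A named numeric vector (names: lag in ms, values: relative
#'   frequency); empty for an empty pattern list.
#' @export
lag_distribution <- function(patterns) {
  if (!length(patterns)) return(numeric(0))
  all_lags <- unlist(lapply(patterns, function(p) {
    l <- p$neuron_lags[, "lag"]
    d <- abs(outer(l, l, `-`))
    d[upper.tri(d)] * p$bin_width
  }))
  tab <- table(all_lags)
  out <- as.numeric(tab) / sum(tab)
  names(out) <- names(tab)
  out
}

#' Serialize a pattern list to JSON
#' @param patterns A pattern list from [mine_patterns()].
#' @param path Optional output path.
#' @return JSON string (invisibly when written to a file).
#' @export
patterns_json <- function(patterns, path = NULL) {
  payload <- lapply(patterns, function(p) {
    list(neurons = unname(p$neuron_lags[, "neuron"]),
         lags_bins = unname(p$neuron_lags[, "lag"]),
         occurrences = p$occurrences,
         size = p$size, span_bins = p$span_bins, bin_width = p$bin_width)
  })
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
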