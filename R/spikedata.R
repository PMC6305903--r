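#' Construct a single spike train
#'
#' A spike train is the ordered sequence of spike times of one neuron within
#' a shared observation window. Times are in milliseconds.
#'
#' @param neuron_id Integer label of the neuron.
#' @param spike_times Numeric vector of spike times in ms, strictly
#'   increasing, all within `[t_start, t_stop]`.
#' @param t_start,t_stop Observation window in ms, `t_stop > t_start`.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(neuron_id, spike_times = numeric(0), t_start, t_stop) {
  neuron_id <- as.integer(neuron_id)
  spike_times <- as.numeric(spike_times)
  t_start <- as.numeric(t_start)
  t_stop <- as.numeric(t_stop)
  stopifnot(length(neuron_id) == 1L, !is.na(neuron_id),
            length(t_start) == 1L, length(t_stop) == 1L)
  if (!(t_stop > t_start)) stop("t_stop must be greater than t_start")
  if (anyNA(spike_times)) stop("spike_times must not contain NA")
  if (length(spike_times) > 1L && any(diff(spike_times) <= 0)) {
    stop("spike_times must be strictly increasing")
  }
  if (length(spike_times) > 0L &&
      (spike_times[1L] < t_start || spike_times[length(spike_times)] > t_stop)) {
    stop("spike times must lie within [t_start, t_stop]")
  }
  structure(list(neuron_id = neuron_id, spike_times = spike_times,
                 t_start = t_start, t_stop = t_stop),
            class = "spike_train")
}

#' Construct a set of parallel spike trains
#'
#' All trains share one observation window; neuron ids are unique. Each
#' neuron carries a population label (`"excitatory"` or `"inhibitory"`),
#' defaulting to excitatory.
#'
#' @param trains List of [spike_train()] objects.
#' @param t_start,t_stop Shared observation window in ms. Defaults to the
#'   window of the first train.
#' @param population Character vector of per-neuron labels, recycled if
#'   length 1.
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(trains, t_start = NULL, t_stop = NULL,
                            population = "excitatory") {
  stopifnot(is.list(trains))
  if (length(trains) > 0L) {
    ok <- vapply(trains, inherits, logical(1), "spike_train")
    if (!all(ok)) stop("all elements of `trains` must be spike_train objects")
  }
  if (is.null(t_start)) {
    t_start <- if (length(trains)) trains[[1L]]$t_start else 0
  }
  if (is.null(t_stop)) {
    t_stop <- if (length(trains)) trains[[1L]]$t_stop else 1
  }
  for (tr in trains) {
    if (tr$t_start != t_start || tr$t_stop != t_stop) {
      stop("all trains must share the observation window")
    }
  }
  ids <- vapply(trains, `[[`, integer(1), "neuron_id")
  if (anyDuplicated(ids)) stop("neuron ids must be unique")
  population <- rep_len(as.character(population), length(trains))
  if (length(population) && !all(population %in% c("excitatory", "inhibitory"))) {
    stop("population labels must be 'excitatory' or 'inhibitory'")
  }
  structure(list(trains = trains, t_start = as.numeric(t_start),
                 t_stop = as.numeric(t_stop), population = population),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  nsp <- sum(vapply(x$trains, function(tr) length(tr$spike_times), integer(1)))
  cat(sprintf("spike_train_set: %d trains (%d excitatory), window [%g, %g] ms, %d spikes\n",
              length(x$trains), sum(x$population == "excitatory"),
              x$t_start, x$t_stop, nsp))
  invisible(x)
}

#' Neuron ids of a spike train set
#' @param set A `spike_train_set`.
#' @return Integer vector of neuron ids in train order.
#' @export
neuron_ids <- function(set) {
  stopifnot(inherits(set, "spike_train_set"))
  vapply(set$trains, `[[`, integer(1), "neuron_id")
}

#' Restrict a spike train set to one population
#' @param set A `spike_train_set`.
#' @param population `"excitatory"` or `"inhibitory"`.
#' @return A `spike_train_set` containing only the selected trains.
#' @export
subset_population <- function(set, population = "excitatory") {
  stopifnot(inherits(set, "spike_train_set"))
  keep <- set$population == match.arg(population, c("excitatory", "inhibitory"))
  spike_train_set(set$trains[keep], set$t_start, set$t_stop,
                  set$population[keep])
}

# number of decimal digits used when printing spike times
.spike_time_digits <- 4L

#' Read parallel spike trains from a two-column text file
#'
#' The file holds one spike per line as `neuron_id time_ms` (whitespace
#' separated). Optional `#`-prefixed header lines carry metadata as
#' `# key value` with keys `t_start`, `t_stop`, `n_neurons`, `n_excitatory`.
#' Ids declared by `n_neurons` but absent from the body yield empty trains
#' (ids are `0 .. n_neurons - 1`; the first `n_excitatory` are labeled
#' excitatory, the rest inhibitory).
#'
#' @param path Path to the spike file.
#' @param t_start,t_stop Observation window in ms; override header values.
#'   If neither header nor argument gives a window, `[0, max time]` is used.
#' @return A [spike_train_set()].
#' @export
read_spike_file <- function(path, t_start = NULL, t_stop = NULL) {
  lines <- readLines(path)
  header <- list()
  body_idx <- integer(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      kv <- strsplit(trimws(sub("^#", "", ln)), "[[:space:]:]+")[[1L]]
      if (length(kv) >= 2L) header[[kv[1L]]] <- suppressWarnings(as.numeric(kv[2L]))
      next
    }
    body_idx <- c(body_idx, i)
  }
  n <- length(body_idx)
  id <- integer(n); tm <- numeric(n)
  for (k in seq_len(n)) {
    i <- body_idx[k]
    fields <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(fields) != 2L || anyNA(vals)) {
      stop(sprintf("malformed spike file line %d: '%s'", i, lines[i]))
    }
    id[k] <- as.integer(vals[1L]); tm[k] <- vals[2L]
  }
  if (is.null(t_start)) t_start <- if (!is.null(header$t_start)) header$t_start else 0
  if (is.null(t_stop)) {
    t_stop <- if (!is.null(header$t_stop)) header$t_stop
              else if (n > 0L) max(tm) else 1
  }
  if (n > 0L && (min(tm) < t_start || max(tm) > t_stop)) {
    bad <- body_idx[which(tm < t_start | tm > t_stop)[1L]]
    stop(sprintf("spike time outside declared window [%g, %g] at line %d",
                 t_start, t_stop, bad))
  }
  all_ids <- sort(unique(id))
  if (!is.null(header$n_neurons)) {
    all_ids <- sort(unique(c(all_ids, seq_len(header$n_neurons) - 1L)))
  }
  trains <- lapply(all_ids, function(j) {
    spike_train(j, sort(tm[id == j]), t_start, t_stop)
  })
  population <- rep("excitatory", length(all_ids))
  if (!is.null(header$n_excitatory)) {
    population <- ifelse(all_ids < header$n_excitatory, "excitatory", "inhibitory")
  }
  spike_train_set(trains, t_start, t_stop, population)
}

#' Write parallel spike trains to a two-column text file
#'
#' Inverse of [read_spike_file()]: a `#` header (t_start, t_stop, n_neurons,
#' n_excitatory) followed by one `neuron_id time_ms` line per spike, times
#' printed with 4 fractional digits.
#'
#' @param set A [spike_train_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spike_file <- function(set, path) {
  stopifnot(inherits(set, "spike_train_set"))
  con <- file(path, "w")
  on.exit(close(con))
  ids <- neuron_ids(set)
  writeLines(c(
    sprintf("# t_start %s", format(set$t_start)),
    sprintf("# t_stop %s", format(set$t_stop)),
    sprintf("# n_neurons %d", length(ids)),
    sprintf("# n_excitatory %d", sum(set$population == "excitatory"))
  ), con)
  for (tr in set$trains) {
    if (length(tr$spike_times)) {
      writeLines(sprintf(paste0("%d %.", .spike_time_digits, "f"),
                         tr$neuron_id, tr$spike_times), con)
    }
  }
  invisible(path)
}

#' Bin parallel spike trains into a count matrix
#'
#' Bin `b` (0-based) covers the half-open interval
#' `[t_start + b*w, t_start + (b+1)*w)`; a trailing partial bin is dropped,
#' so the matrix has `N = floor((t_stop - t_start)/w)` columns. Spikes
#' exactly at `t_stop` fall outside the last retained bin and are excluded.
#'
#' @param set A [spike_train_set()].
#' @param bin_width_ms Bin width in ms, `0 < w < t_stop - t_start`.
#' @return An object of class `binned_matrix` with fields `counts`
#'   (neurons x bins integer matrix, rownames = neuron ids), `bin_width`,
#'   `t_start` and `neuron_ids`.
#' @export
bin_spike_trains <- function(set, bin_width_ms) {
  stopifnot(inherits(set, "spike_train_set"))
  w <- as.numeric(bin_width_ms)
  stopifnot(length(w) == 1L, is.finite(w), w > 0)
  span <- set$t_stop - set$t_start
  if (w >= span) stop("bin width must be smaller than the observation window")
  n_bins <- floor(span / w)
  ids <- neuron_ids(set)
  counts <- matrix(0L, nrow = length(ids), ncol = n_bins)
  for (k in seq_along(set$trains)) {
    tt <- set$trains[[k]]$spike_times
    if (!length(tt)) next
    b <- floor((tt - set$t_start) / w)
    b <- b[b < n_bins]
    if (length(b)) counts[k, ] <- tabulate(b + 1L, nbins = n_bins)
  }
  rownames(counts) <- ids
  structure(list(counts = counts, bin_width = w, t_start = set$t_start,
                 neuron_ids = ids),
            class = "binned_matrix")
}

#' @export
print.binned_matrix <- function(x, ...) {
  cat(sprintf("binned_matrix: %d neurons x %d bins at %g ms\n",
              nrow(x$counts), ncol(x$counts), x$bin_width))
  invisible(x)
}
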