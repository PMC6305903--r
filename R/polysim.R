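#' Izhikevich neuron parameters by firing class
#'
#' Canonical parameter sets of the two-variable Izhikevich model:
#' regular spiking (a = 0.02, b = 0.2, c = -65, d = 8) for excitatory
#' neurons and fast spiking (a = 0.1, b = 0.2, c = -65, d = 2) for
#' inhibitory neurons, with a spike cut-off of v_peak = 30 (mV-like units).
#'
#' @param class `"regular_spiking"` or `"fast_spiking"`.
#' @return A list with `a`, `b`, `c`, `d`, `v_peak` and `class`.
#' @export
neuron_params <- function(class = c("regular_spiking", "fast_spiking")) {
  class <- match.arg(class)
  p <- switch(class,
    regular_spiking = list(a = 0.02, b = 0.2, c = -65, d = 8),
    fast_spiking    = list(a = 0.1,  b = 0.2, c = -65, d = 2))
  c(p, list(v_peak = 30, class = class))
}

#' Build a polychronization-model network
#'
#' Random network of `n_neurons` Izhikevich neurons with `exc_ratio` times
#' more excitatory (regular spiking) than inhibitory (fast spiking)
#' neurons. Every neuron projects to exactly `out_degree` distinct targets
#' drawn without replacement; inhibitory neurons target only the excitatory
#' population; no self-connections. Excitatory delays are drawn from a
#' discrete uniform distribution on 1..20 ms, inhibitory delays are 1 ms.
#' Weights start at `w_exc` (excitatory) and `w_inh` (inhibitory),
#' interpretable in pA.
#'
#' @param n_neurons Total number of neurons (default 1000).
#' @param exc_ratio Ratio of excitatory to inhibitory neurons (default 4,
#'   i.e. 800 excitatory and 200 inhibitory).
#' @param out_degree Out-degree of every neuron (default 100).
#' @param w_exc,w_inh Initial synaptic weights.
#' @param delay_max Maximum excitatory delay in ms (default 20).
#' @param seed Integer seed; the network is fully determined by
#'   `(seed, arguments)`.
#' @return An object of class `network_state` with per-neuron target lists
#'   `targets`, matching `delays` and `weights`, and the counts
#'   `n_neurons`, `n_excitatory`.
#' @export
build_network <- function(n_neurons = 1000L, exc_ratio = 4, out_degree = 100L,
                          w_exc = 6, w_inh = -5, delay_max = 20L,
                          seed = NULL) {
  n_neurons <- as.integer(n_neurons)
  out_degree <- as.integer(out_degree)
  n_exc <- as.integer(round(n_neurons * exc_ratio / (exc_ratio + 1)))
  if (out_degree > n_neurons - 1L || out_degree > n_exc) {
    stop("out_degree exceeds the number of available targets")
  }
  with_seed(seed, {
    targets <- vector("list", n_neurons)
    delays <- vector("list", n_neurons)
    weights <- vector("list", n_neurons)
    exc_ids <- seq_len(n_exc)
    for (i in seq_len(n_neurons)) {
      if (i <= n_exc) {
        pool <- setdiff(seq_len(n_neurons), i)
        targets[[i]] <- sample(pool, out_degree)
        delays[[i]] <- sample.int(delay_max, out_degree, replace = TRUE)
        weights[[i]] <- rep(w_exc, out_degree)
      } else {
        targets[[i]] <- sample(exc_ids, out_degree)
        delays[[i]] <- rep(1L, out_degree)
        weights[[i]] <- rep(w_inh, out_degree)
      }
    }
    structure(list(targets = targets, delays = delays, weights = weights,
                   n_neurons = n_neurons, n_excitatory = n_exc),
              class = "network_state")
  })
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf("network_state: %d neurons (%d excitatory), out-degree %d\n",
              x$n_neurons, x$n_excitatory, length(x$targets[[1L]])))
  invisible(x)
}

#' One semi-implicit Euler substep of the Izhikevich model
#'
#' Advances `v' = 0.04 v^2 + 5 v + 140 - u + I`, `u' = a (b v - u)` by a
#' substep of size `h` ms: `v` is updated first, then `u` from the new `v`.
#' On `v >= v_peak` the neuron spikes and is reset (`v <- c`,
#' `u <- u + d`). Vectorized over neurons; the compiled simulator applies
#' the identical update.
#'
#' @param v,u State variables (vectors).
#' @param params A list of parameter vectors `a`, `b`, `c`, `d`, `v_peak`
#'   (scalars are recycled).
#' @param I Input current (pA-interpretable).
#' @param h Substep size in ms (1 or 1/16).
#' @return A list with updated `v`, `u` and logical `spiked`.
#' @export
izhikevich_step <- function(v, u, params, I, h) {
  if (any(!is.finite(v)) || any(!is.finite(u))) {
    stop("non-finite neuron state: simulation aborted")
  }
  v_new <- v + h * (0.04 * v^2 + 5 * v + 140 - u + I)
  u_new <- u + h * params$a * (params$b * v_new - u)
  spiked <- v_new >= params$v_peak
  v_new[spiked] <- rep_len(params$c, length(v_new))[spiked]
  u_new[spiked] <- u_new[spiked] + rep_len(params$d, length(u_new))[spiked]
  list(v = v_new, u = u_new, spiked = spiked)
}

#' Simulate a network with frozen weights
#'
#' Frozen-weight replay protocol: no plasticity, the network is driven by
#' an external 20 pA current pulse injected into one uniformly chosen
#' neuron per 1 ms step. Within each 1 ms step the neuron dynamics are
#' advanced by `substeps` semi-implicit Euler substeps with threshold
#' detection per substep; spike times are recorded on the 1 ms grid.
#' Synaptic charge arrives at the target `delay` ms after the presynaptic
#' spike (delta-current synapses; simultaneous arrivals sum linearly) and
#' acts during that step.
#'
#' Supplying the `input_record` of a previous run together with the same
#' network reproduces its spikes exactly, which implements the replay
#' protocol used to compare implementations across saved network states.
#'
#' @param network A [build_network()] result.
#' @param duration_s Simulated time in seconds (default 60).
#' @param input_amplitude Stimulus amplitude in pA (default 20).
#' @param seed Integer seed for the input series (ignored when
#'   `input_record` is given).
#' @param substeps Euler substeps per 1 ms (default 16).
#' @param input_record Optional `input_record` from a previous run.
#' @return A list with `spikes` (a [spike_train_set()], ids `0..n-1`, the
#'   first `n_excitatory` excitatory) and `input` (an `input_record`:
#'   data frame of `step`, `neuron_id` plus the amplitude attribute).
#' @export
simulate_network <- function(network, duration_s = 60, input_amplitude = 20,
                             seed = NULL, substeps = 16L,
                             input_record = NULL) {
  stopifnot(inherits(network, "network_state"))
  n_steps <- as.integer(round(duration_s * 1000))
  if (is.null(input_record)) {
    chosen <- with_seed(seed, sample.int(network$n_neurons, n_steps,
                                         replace = TRUE))
    input_record <- structure(
      data.frame(step = seq_len(n_steps) - 1L, neuron_id = chosen - 1L),
      amplitude = input_amplitude, class = c("input_record", "data.frame"))
  } else {
    stopifnot(inherits(input_record, "input_record"))
    if (nrow(input_record) < n_steps) {
      stop("input_record is shorter than the requested duration")
    }
    chosen <- input_record$neuron_id[seq_len(n_steps)] + 1L
    input_amplitude <- attr(input_record, "amplitude")
  }
  deg <- lengths(network$targets)
  ptr <- c(0L, cumsum(deg))
  params_e <- neuron_params("regular_spiking")
  params_i <- neuron_params("fast_spiking")
  is_exc <- seq_len(network$n_neurons) <= network$n_excitatory
  a <- ifelse(is_exc, params_e$a, params_i$a)
  b <- ifelse(is_exc, params_e$b, params_i$b)
  cr <- ifelse(is_exc, params_e$c, params_i$c)
  dr <- ifelse(is_exc, params_e$d, params_i$d)
  res <- simulate_core(network$n_neurons, ptr,
                       unlist(network$targets, use.names = FALSE) - 1L,
                       as.integer(unlist(network$delays, use.names = FALSE)),
                       as.numeric(unlist(network$weights, use.names = FALSE)),
                       a, b, cr, dr, chosen - 1L, input_amplitude,
                       n_steps, as.integer(substeps), 30.0, -65.0)
  if (res$aborted) {
    stop(sprintf(paste0("runaway activity: mean population rate %.0f Hz ",
                        "sustained over 1 s (step %d); simulation aborted"),
                 res$abort_rate, res$abort_step))
  }
  ids <- seq_len(network$n_neurons) - 1L
  trains <- lapply(ids, function(j) {
    spike_train(j, res$times[res$neurons == j], 0, n_steps)
  })
  spikes <- spike_train_set(trains, 0, n_steps,
                            ifelse(is_exc, "excitatory", "inhibitory"))
  list(spikes = spikes, input = input_record)
}

#' Generate jittered network states for the multi-state protocol
#'
#' Emulates the protocol of analyzing one network at several training
#' stages: `n_states` copies of the base network whose excitatory weights
#' are independently jittered (additive Gaussian noise, clipped to
#' `[0, w_max]`), each to be simulated with the *same* input record.
#' Inhibitory weights are left unchanged (they are non-plastic in the
#' underlying model).
#'
#' @param network A [build_network()] result.
#' @param n_states Number of states (default 5).
#' @param jitter_sd SD of the additive weight jitter (default 1).
#' @param w_max Upper clip for excitatory weights (default 10).
#' @param seed Integer seed.
#' @return A list of `network_state` objects.
#' @export
network_states <- function(network, n_states = 5L, jitter_sd = 1,
                           w_max = 10, seed = NULL) {
  stopifnot(inherits(network, "network_state"))
  with_seed(seed, {
    lapply(seq_len(n_states), function(s) {
      st <- network
      for (i in seq_len(network$n_excitatory)) {
        w <- st$weights[[i]] + stats::rnorm(length(st$weights[[i]]),
                                            sd = jitter_sd)
        st$weights[[i]] <- pmin(pmax(w, 0), w_max)
      }
      st
    })
  })
}

#' Save a network state to a plain-text file
#'
#' One header plus three sections: `A` (out-connection target lists), `D`
#' (delays, ms) and `W` (weights), one neuron per line, space-delimited.
#'
#' @param network A `network_state`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_state <- function(network, path) {
  stopifnot(inherits(network, "network_state"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# spikeval network_state v1",
               sprintf("# n_neurons %d", network$n_neurons),
               sprintf("# n_excitatory %d", network$n_excitatory)), con)
  fmt_row <- function(x) paste(format(x, scientific = FALSE, trim = TRUE),
                               collapse = " ")
  for (section in c("A", "D", "W")) {
    writeLines(sprintf("# section %s", section), con)
    field <- switch(section, A = "targets", D = "delays", W = "weights")
    writeLines(vapply(network[[field]], fmt_row, character(1)), con)
  }
  invisible(path)
}

#' Load a network state written by [save_state()]
#'
#' @param path Path to a state file.
#' @return A `network_state`.
#' @export
load_state <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1L], "# spikeval network_state")) {
    stop("not a spikeval network_state file (missing header)")
  }
  meta <- list()
  sections <- list(A = character(0), D = character(0), W = character(0))
  current <- NULL
  for (ln in lines[-1L]) {
    if (startsWith(ln, "# section ")) {
      current <- sub("^# section ", "", ln)
      if (!current %in% names(sections)) stop("unknown section: ", current)
    } else if (startsWith(ln, "#")) {
      kv <- strsplit(trimws(sub("^#", "", ln)), "[[:space:]]+")[[1L]]
      meta[[kv[1L]]] <- as.numeric(kv[2L])
    } else if (!is.null(current)) {
      sections[[current]] <- c(sections[[current]], ln)
    }
  }
  n <- as.integer(meta$n_neurons)
  if (is.na(n) || any(lengths(sections) != n)) {
    stop("corrupted network_state file: section lengths do not match n_neurons")
  }
  parse_rows <- function(rows, cast) {
    lapply(rows, function(r) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(r), "[[:space:]]+")[[1L]]))
      if (anyNA(v)) stop("corrupted network_state file: non-numeric entry")
      cast(v)
    })
  }
  structure(list(targets = parse_rows(sections$A, as.integer),
                 delays = parse_rows(sections$D, as.integer),
                 weights = parse_rows(sections$W, as.numeric),
                 n_neurons = n,
                 n_excitatory = as.integer(meta$n_excitatory)),
            class = "network_state")
}

#' Write an input record as two-column text
#' @param input An `input_record` from [simulate_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_input_record <- function(input, path) {
  stopifnot(inherits(input, "input_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# amplitude %g", attr(input, "amplitude")), con)
  writeLines(sprintf("%d %d", input$step, input$neuron_id), con)
  invisible(path)
}

#' Read an input record written by [write_input_record()]
#' @param path Path to the file.
#' @return An `input_record`.
#' @export
read_input_record <- function(path) {
  lines <- readLines(path)
  amp <- 20
  hdr <- grepl("^#", lines)
  for (ln in lines[hdr]) {
    kv <- strsplit(trimws(sub("^#", "", ln)), "[[:space:]]+")[[1L]]
    if (kv[1L] == "amplitude") amp <- as.numeric(kv[2L])
  }
  body <- lines[!hdr & nzchar(trimws(lines))]
  mat <- do.call(rbind, lapply(strsplit(trimws(body), "[[:space:]]+"),
                               as.integer))
  structure(data.frame(step = mat[, 1L], neuron_id = mat[, 2L]),
            amplitude = amp, class = c("input_record", "data.frame"))
}
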