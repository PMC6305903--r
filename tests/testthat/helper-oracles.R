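# independent brute-force oracles the implementations are checked against

# literal double loop for R_xy(tau) with zero padding and 1/N normalization
oracle_cross_correlation <- function(x, y, max_lag) {
  n <- length(x)
  sapply(-max_lag:max_lag, function(tau) {
    acc <- 0
    for (t in seq_len(n)) {
      tt <- t + tau
      if (tt >= 1 && tt <= n) acc <- acc + x[t] * y[tt]
    }
    acc / n
  })
}

# triple loop for the integral correlation P_xy of a count matrix
oracle_integral_correlation <- function(m, delta) {
  n <- nrow(m); N <- ncol(m)
  mu <- rowMeans(m)
  sds <- sqrt(rowMeans(m^2) - mu^2)
  P <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (sds[i] == 0 || sds[j] == 0) next
      acc <- 0
      for (tau in -delta:delta) {
        r <- 0
        for (t in seq_len(N)) {
          tt <- t + tau
          if (tt >= 1 && tt <= N) r <- r + m[i, t] * m[j, tt]
        }
        acc <- acc + (r / N - mu[i] * mu[j]) / (sds[i] * sds[j])
      }
      P[i, j] <- acc
    }
  }
  P
}

# exhaustive closed-itemset enumeration for tiny pattern-mining fixtures:
# every closed itemset is an intersection of a nonempty subset of window
# transactions, i.e. the closure system generated by pairwise intersection.
oracle_patterns <- function(set, config) {
  w <- config$bin_width
  n_bins <- floor((set$t_stop - set$t_start) / w)
  n_lags <- 1L
  while (n_lags * w < config$max_span) n_lags <- n_lags + 1L
  n_neurons <- length(set$trains)
  bins <- lapply(set$trains, function(tr) {
    b <- unique(floor((tr$spike_times - set$t_start) / w))
    as.integer(b[b < n_bins])
  })
  trans <- lapply(seq_len(n_bins) - 1L, function(win) {
    items <- integer(0)
    for (l in seq_len(n_lags) - 1L) {
      for (nn in seq_len(n_neurons)) {
        if ((win + l) %in% bins[[nn]]) {
          items <- c(items, l * n_neurons + (nn - 1L))
        }
      }
    }
    sort(items)
  })
  nonempty <- unique(trans[lengths(trans) > 0])
  closed <- nonempty
  seen <- new.env(parent = emptyenv())
  for (a in closed) assign(paste(a, collapse = ","), TRUE, envir = seen)
  worklist <- closed
  while (length(worklist)) {
    a <- worklist[[1L]]
    worklist <- worklist[-1L]
    for (b in nonempty) {
      i <- intersect(a, b)
      if (length(i)) {
        k <- paste(i, collapse = ",")
        if (is.null(seen[[k]])) {
          seen[[k]] <- TRUE
          closed <- c(closed, list(sort(i)))
          worklist <- c(worklist, list(sort(i)))
        }
      }
    }
  }
  out <- list()
  for (items in closed) {
    occ <- which(vapply(trans, function(tt) all(items %in% tt), logical(1))) - 1L
    lags <- items %/% n_neurons
    if (length(occ) >= config$min_occurrences &&
        length(items) >= config$min_size &&
        min(lags) == 0L) {
      out[[length(out) + 1L]] <- list(items = sort(items), tids = sort(occ))
    }
  }
  out
}

# canonical string form of a pattern list for set comparison
pattern_keys <- function(patterns, n_neurons, ids) {
  vapply(patterns, function(p) {
    if (!is.null(p$neuron_lags)) {
      neuron <- p$neuron_lags[, "neuron"]
      lag <- p$neuron_lags[, "lag"]
      items <- sort(lag * n_neurons + match(neuron, ids) - 1L)
      occ <- p$occurrences
    } else {
      items <- p$items
      occ <- p$tids
    }
    paste(paste(items, collapse = ","), "|", paste(sort(occ), collapse = ","))
  }, character(1))
}
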