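#' Configuration of a model-to-model comparison
#'
#' Fixes every free parameter of the statistical battery so that a
#' comparison is fully reproducible from `(inputs, config, seeds)`.
#'
#' @param measures Subset of `FR`, `LV`, `ISI`, `CC`, `RC`, `P`, `lambda`,
#'   `patterns`, `spectrum`.
#' @param cc_bin_ms Bin width for the fine-scale correlation matrix (2 ms).
#' @param rc_bin_ms Bin width for the coarse-scale rate correlation (100 ms).
#' @param p_delta_bins Lag half-window for the integral correlation
#'   (Delta = 50 bins at the CC bin width, i.e. lags up to 100 ms).
#' @param mining A [mining_config()].
#' @param n_permutations Shuffles for the similarity surrogate null.
#' @param seed Seed for the surrogate null.
#' @param excitatory_only If `TRUE` (default) only the excitatory
#'   population enters the analysis.
#' @param t_test_measures Measures the parametric t-test is applied to;
#'   by default the approximately normal ones: FR, LV, RC and log(ISI)
#'   (the ISI t-test runs on log-transformed intervals). All measures
#'   always get the nonparametric KS and MWU tests.
#' @param bonferroni If `TRUE`, p-values in the report are Bonferroni
#'   corrected across measures (off by default).
#' @param pop_hist_bin_ms Bin width of the population-rate histogram.
#' @return An object of class `comparison_config`.
#' @export
comparison_config <- function(measures = c("FR", "LV", "ISI", "CC", "RC",
                                           "P", "lambda", "patterns",
                                           "spectrum"),
                              cc_bin_ms = 2, rc_bin_ms = 100,
                              p_delta_bins = 50L,
                              mining = mining_config(),
                              n_permutations = 10000L, seed = 1L,
                              excitatory_only = TRUE,
                              t_test_measures = c("FR", "LV", "RC", "ISI"),
                              bonferroni = FALSE,
                              pop_hist_bin_ms = 60) {
  all_measures <- c("FR", "LV", "ISI", "CC", "RC", "P", "lambda",
                    "patterns", "spectrum")
  measures <- match.arg(measures, all_measures, several.ok = TRUE)
  stopifnot(cc_bin_ms > 0, rc_bin_ms > 0, p_delta_bins >= 0,
            inherits(mining, "mining_config"), n_permutations >= 1)
  structure(list(measures = measures, cc_bin_ms = cc_bin_ms,
                 rc_bin_ms = rc_bin_ms,
                 p_delta_bins = as.integer(p_delta_bins),
                 mining = mining,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed),
                 excitatory_only = isTRUE(excitatory_only),
                 t_test_measures = t_test_measures,
                 bonferroni = isTRUE(bonferroni),
                 pop_hist_bin_ms = pop_hist_bin_ms),
            class = "comparison_config")
}

#' Read a comparison configuration from YAML
#'
#' Recognized keys mirror the arguments of [comparison_config()]; the
#' `mining` key holds a nested map with [mining_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return A `comparison_config`.
#' @export
read_comparison_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$mining)) y$mining <- do.call(mining_config, y$mining)
  do.call(comparison_config, y)
}

# distribution-valued measures (effect size + hypothesis tests apply)
.dist_measures <- c("FR", "LV", "ISI", "CC", "RC", "P", "lambda")

#' Extract the statistical battery from one spike dataset
#'
#' Computes the configured measure distributions (and matrices, patterns,
#' spectrum) from one dataset. Both datasets of a comparison go through
#' this identical code path so that scoring differences cannot stem from
#' the extraction.
#'
#' @param spikes A [spike_train_set()].
#' @param config A [comparison_config()].
#' @return An object of class `prediction` holding `distributions` (per
#'   measure [measure_distribution()]), `matrices` (CC/RC/P
#'   `correlation_matrix` objects as configured), `patterns`, `spectrum`,
#'   and bookkeeping fields.
#' @export
extract_prediction <- function(spikes, config = comparison_config()) {
  stopifnot(inherits(spikes, "spike_train_set"),
            inherits(config, "comparison_config"))
  if (config$excitatory_only) spikes <- subset_population(spikes, "excitatory")
  out <- list(distributions = list(), matrices = list(), patterns = NULL,
              spectrum = NULL, n_units = length(spikes$trains),
              t_start = spikes$t_start, t_stop = spikes$t_stop,
              neuron_ids = neuron_ids(spikes))
  m <- config$measures
  for (mono in intersect(c("FR", "LV", "ISI"), m)) {
    out$distributions[[mono]] <- monovariate_distribution(spikes, mono)
  }
  need_cc <- any(c("CC", "P") %in% m)
  if (need_cc) {
    binned_cc <- bin_spike_trains(spikes, config$cc_bin_ms)
    if ("CC" %in% m) {
      cm <- correlation_matrix(binned_cc, kind = "CC")
      out$matrices$CC <- cm
      out$distributions$CC <- matrix_distribution(cm, "CC")
    }
    if ("P" %in% m) {
      pm <- integral_correlation_matrix(binned_cc, config$p_delta_bins)
      out$matrices$P <- pm
      out$distributions$P <- matrix_distribution(pm, "P")
    }
    rm(binned_cc)
  }
  if (any(c("RC", "lambda") %in% m)) {
    binned_rc <- bin_spike_trains(spikes, config$rc_bin_ms)
    rc <- correlation_matrix(binned_rc, kind = "RC")
    if ("RC" %in% m) {
      out$matrices$RC <- rc
      out$distributions$RC <- matrix_distribution(rc, "RC")
    }
    if ("lambda" %in% m) {
      valid_rc <- drop_invalid_units(rc)
      es <- eigendecompose(valid_rc)
      out$distributions$lambda <- measure_distribution(
        "lambda", es$values, nrow(rc$values) - nrow(valid_rc$values))
    }
  }
  if ("patterns" %in% m) {
    pats <- mine_patterns(spikes, config$mining)
    out$patterns <- list(patterns = pats, count = length(pats),
                         lag_histogram = lag_distribution(pats))
  }
  if ("spectrum" %in% m) {
    out$spectrum <- welch_population_spectrum(spikes)
  }
  structure(out, class = "prediction")
}

# off-diagonal valid entries of a correlation matrix as a distribution
matrix_distribution <- function(cm, name) {
  ut <- upper.tri(cm$values)
  vals <- cm$values[ut & cm$valid_mask]
  measure_distribution(name, vals, sum(ut & !cm$valid_mask))
}

#' Compare two spike datasets with an identical statistical battery
#'
#' Runs [extract_prediction()] on both datasets with the same
#' configuration, scores every distribution-valued measure with the effect
#' size and two-sample hypothesis tests, quantifies the similarity of the
#' CC/RC correlation structures against a neuron-relabeling surrogate
#' null, and reports pattern counts and lag histograms. Deterministic
#' under fixed seeds.
#'
#' @param spikes_a,spikes_b Two [spike_train_set()] objects with equal
#'   window length. When label-sensitive scores (similarity) are enabled,
#'   the neuron labeling must match.
#' @param config A [comparison_config()].
#' @return An object of class `comparison_report`.
#' @export
judge <- function(spikes_a, spikes_b, config = comparison_config()) {
  stopifnot(inherits(spikes_a, "spike_train_set"),
            inherits(spikes_b, "spike_train_set"))
  dur_a <- spikes_a$t_stop - spikes_a$t_start
  dur_b <- spikes_b$t_stop - spikes_b$t_start
  if (abs(dur_a - dur_b) > 1e-9) {
    stop("incompatible observation windows: durations differ")
  }
  similarity_on <- any(c("CC", "RC") %in% config$measures)
  pred_a <- extract_prediction(spikes_a, config)
  pred_b <- extract_prediction(spikes_b, config)
  if (similarity_on && !identical(pred_a$neuron_ids, pred_b$neuron_ids)) {
    stop("similarity scores need identical neuron labeling in both datasets")
  }
  measures <- list()
  for (nm in intersect(.dist_measures, config$measures)) {
    da <- pred_a$distributions[[nm]]
    db <- pred_b$distributions[[nm]]
    va <- da$values; vb <- db$values
    tests <- list(ks = two_sample_test(va, vb, "ks"),
                  mwu = two_sample_test(va, vb, "mwu"))
    if (nm %in% config$t_test_measures) {
      ta <- va; tb <- vb
      if (nm == "ISI") {
        ta <- log(va[va > 0]); tb <- log(vb[vb > 0])
      }
      tests$t <- tryCatch(two_sample_test(ta, tb, "t"),
                          error = function(e) {
                            structure(list(test = "t", statistic = NA_real_,
                                           p_value = NA_real_),
                                      class = "hypothesis_test_result")
                          })
    }
    if (config$bonferroni) {
      k <- length(intersect(.dist_measures, config$measures))
      tests <- lapply(tests, function(tt) {
        tt$p_value <- min(1, tt$p_value * k)
        tt
      })
    }
    measures[[nm]] <- list(
      effect_size = effect_size(va, vb),
      tests = tests,
      a = list(values = va, n = length(va), n_excluded = da$n_excluded,
               mean = mean(va), sd = stats::sd(va)),
      b = list(values = vb, n = length(vb), n_excluded = db$n_excluded,
               mean = mean(vb), sd = stats::sd(vb)))
  }
  similarity <- list()
  if (similarity_on) {
    for (kind in intersect(c("CC", "RC"), config$measures)) {
      ca <- pred_a$matrices[[kind]]
      cb <- pred_b$matrices[[kind]]
      keep <- diag(ca$valid_mask) & diag(cb$valid_mask)
      if (sum(keep) >= 2L) {
        sa <- subset_correlation_matrix(ca, keep)
        sb <- subset_correlation_matrix(cb, keep)
        similarity[[kind]] <- surrogate_similarity_null(
          sa, sb, config$n_permutations, config$seed)
      }
    }
  }
  patterns <- NULL
  if ("patterns" %in% config$measures) {
    patterns <- list(
      a = pred_a$patterns[c("count", "lag_histogram")],
      b = pred_b$patterns[c("count", "lag_histogram")])
  }
  spectrum <- NULL
  if ("spectrum" %in% config$measures) {
    spectrum <- list(a = pred_a$spectrum, b = pred_b$spectrum)
  }
  structure(list(measures = measures, similarity = similarity,
                 patterns = patterns, spectrum = spectrum,
                 config = config,
                 software_version = as.character(packageVersion("spikeval")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "comparison_report")
}

subset_correlation_matrix <- function(C, keep) {
  correlation_matrix_object(C$values[keep, keep, drop = FALSE], C$bin_width,
                            C$kind, C$valid_mask[keep, keep, drop = FALSE],
                            C$neuron_ids[keep])
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report\n")
  for (nm in names(x$measures)) {
    m <- x$measures[[nm]]
    ps <- vapply(m$tests, `[[`, numeric(1), "p_value")
    cat(sprintf("  %-6s d = %+.3f  %s\n", nm, m$effect_size$d,
                paste(sprintf("p_%s = %.3g", names(ps), ps), collapse = "  ")))
  }
  for (kind in names(x$similarity)) {
    s <- x$similarity[[kind]]
    cat(sprintf("  %s similarity = %.3f (null %.3f +/- %.3f, z = %.1f)\n",
                kind, s$score, s$null_mean, s$null_sd, s$z))
  }
  if (!is.null(x$patterns)) {
    cat(sprintf("  patterns: %d vs %d\n", x$patterns$a$count,
                x$patterns$b$count))
  }
  invisible(x)
}

#' Serialize a comparison report to JSON
#'
#' The report embeds the resolved configuration and the raw per-measure
#' distributions, so scores can be recomputed from the file alone.
#'
#' @param report A `comparison_report`.
#' @param path Optional output path.
#' @return JSON string (invisibly when written to a file).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "comparison_report"))
  payload <- rapply(unclass(report), function(x) {
    if (is.numeric(x)) ifelse(is.infinite(x), sign(x) * .Machine$double.xmax, x)
    else x
  }, how = "replace")
  payload$config$mining <- unclass(payload$config$mining)
  payload$config <- unclass(payload$config)
  for (nm in names(payload$measures)) {
    payload$measures[[nm]]$effect_size <-
      unclass(payload$measures[[nm]]$effect_size)
    payload$measures[[nm]]$tests <-
      lapply(payload$measures[[nm]]$tests, unclass)
  }
  payload$similarity <- lapply(payload$similarity, unclass)
  # I(17) significant digits: doubles survive the JSON round trip exactly,
  # so scores recomputed from the file match the report bit for bit
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                         na = "null", force = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Re-score a report from its serialized raw distributions
#'
#' Recomputes effect sizes and hypothesis-test p-values from the raw
#' per-measure values stored in a report JSON file, reproducing the values
#' in the report.
#'
#' @param path Path to a JSON file written by [report_to_json()].
#' @return A list per measure with `d` and the per-test `p_value`s.
#' @export
rescore_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list()
  for (nm in names(rep$measures)) {
    m <- rep$measures[[nm]]
    va <- as.numeric(m$a$values); vb <- as.numeric(m$b$values)
    tests <- list(ks = two_sample_test(va, vb, "ks")$p_value,
                  mwu = two_sample_test(va, vb, "mwu")$p_value)
    if (!is.null(m$tests$t)) {
      ta <- va; tb <- vb
      if (nm == "ISI") {
        ta <- log(va[va > 0]); tb <- log(vb[vb > 0])
      }
      tests$t <- tryCatch(two_sample_test(ta, tb, "t")$p_value,
                          error = function(e) NA_real_)
    }
    out[[nm]] <- list(d = effect_size(va, vb)$d, p_values = tests)
  }
  out
}
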