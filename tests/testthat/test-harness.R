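fixture_pair <- function(seed = 50, n_neurons = 60, duration_s = 4) {
  net <- build_network(n_neurons = n_neurons, out_degree = n_neurons / 3,
                       seed = seed)
  states <- network_states(net, n_states = 2, seed = seed + 1)
  input <- simulate_network(net, duration_s = duration_s,
                            seed = seed + 2)$input
  list(a = simulate_network(states[[1]], duration_s = duration_s,
                            input_record = input)$spikes,
       b = simulate_network(states[[2]], duration_s = duration_s,
                            input_record = input)$spikes)
}

small_config <- function(...) {
  comparison_config(n_permutations = 300L, seed = 7L,
                    mining = mining_config(min_occurrences = 3, min_size = 4),
                    ...)
}

test_that("extract_prediction matches the individual measure operations", {
  set.seed(61)
  trains <- lapply(1:10, function(i) poisson_train_fast(i - 1L, 8, 10000))
  set <- spike_train_set(trains, 0, 10000)
  cfg <- small_config()
  pred <- extract_prediction(set, cfg)
  expect_equal(pred$distributions$FR$values,
               vapply(set$trains, firing_rate, numeric(1)))
  expect_equal(pred$distributions$LV$values,
               monovariate_distribution(set, "LV")$values)
  cc <- correlation_matrix(bin_spike_trains(set, 2))
  expect_equal(pred$matrices$CC$values, cc$values)
  expect_equal(pred$distributions$CC$values,
               cc$values[upper.tri(cc$values) & cc$valid_mask])
  rc <- correlation_matrix(bin_spike_trains(set, 100))
  expect_equal(pred$distributions$lambda$values,
               eigendecompose(drop_invalid_units(rc))$values)
  P <- integral_correlation_matrix(bin_spike_trains(set, 2), 50)
  expect_equal(pred$matrices$P$values, P$values)
  expect_equal(pred$patterns$count,
               count_patterns(set, cfg$mining))
  expect_equal(pred$spectrum, welch_population_spectrum(set))
})

test_that("the excitatory-only switch filters the population", {
  trains <- lapply(0:9, function(j) regular_train(j, 100 + j, 5000))
  set <- spike_train_set(trains, 0, 5000,
                         rep(c("excitatory", "inhibitory"), each = 5))
  cfg <- small_config(measures = "FR")
  expect_length(extract_prediction(set, cfg)$distributions$FR$values, 5L)
  cfg_all <- small_config(measures = "FR", excitatory_only = FALSE)
  expect_length(extract_prediction(set, cfg_all)$distributions$FR$values, 10L)
})

test_that("self-comparison yields identity scores on every measure", {
  x <- fixture_pair()$a
  rep <- judge(x, x, small_config())
  for (nm in names(rep$measures)) {
    m <- rep$measures[[nm]]
    expect_equal(m$effect_size$d, 0)
    expect_equal(m$tests$ks$statistic, 0)
    expect_equal(m$tests$ks$p_value, 1)
  }
  for (kind in names(rep$similarity)) {
    expect_equal(rep$similarity[[kind]]$score, 1.0)
  }
  expect_equal(rep$patterns$a$count, rep$patterns$b$count)
})

test_that("swapping the inputs negates d and keeps nonparametric p-values", {
  pr <- fixture_pair()
  cfg <- small_config(measures = c("FR", "LV", "ISI", "CC", "RC"))
  r_ab <- judge(pr$a, pr$b, cfg)
  r_ba <- judge(pr$b, pr$a, cfg)
  for (nm in names(r_ab$measures)) {
    expect_equal(r_ab$measures[[nm]]$effect_size$d,
                 -r_ba$measures[[nm]]$effect_size$d)
    expect_equal(r_ab$measures[[nm]]$tests$ks$p_value,
                 r_ba$measures[[nm]]$tests$ks$p_value)
    expect_equal(r_ab$measures[[nm]]$tests$mwu$p_value,
                 r_ba$measures[[nm]]$tests$mwu$p_value)
  }
})

test_that("two jittered network states give a finite, small-effect report", {
  pr <- fixture_pair()
  rep <- judge(pr$a, pr$b, small_config())
  ds <- vapply(rep$measures, function(m) m$effect_size$d, numeric(1))
  expect_true(all(is.finite(ds)))
  expect_true(all(abs(ds) < 3))
  for (nm in names(rep$measures)) {
    for (tt in rep$measures[[nm]]$tests) {
      if (!is.na(tt$p_value)) {
        expect_gte(tt$p_value, 0)
        expect_lte(tt$p_value, 1)
      }
    }
  }
})

test_that("reports serialize to JSON and re-score identically from raw values", {
  pr <- fixture_pair()
  cfg <- small_config(measures = c("FR", "LV", "ISI", "RC"))
  rep <- judge(pr$a, pr$b, cfg)
  path <- withr::local_tempfile(fileext = ".json")
  report_to_json(rep, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$config$rc_bin_ms, 100)
  expect_equal(parsed$software_version,
               as.character(packageVersion("spikeval")))
  rescored <- rescore_report(path)
  for (nm in names(rep$measures)) {
    expect_equal(rescored[[nm]]$d, rep$measures[[nm]]$effect_size$d,
                 tolerance = 1e-12)
    expect_equal(rescored[[nm]]$p_values$ks,
                 rep$measures[[nm]]$tests$ks$p_value, tolerance = 1e-12)
    expect_equal(rescored[[nm]]$p_values$mwu,
                 rep$measures[[nm]]$tests$mwu$p_value, tolerance = 1e-12)
  }
})

test_that("judge rejects incompatible inputs", {
  pr <- fixture_pair()
  shorter <- spike_train_set(lapply(pr$b$trains, function(tr) {
    spike_train(tr$neuron_id, tr$spike_times[tr$spike_times < 2000], 0, 2000)
  }), 0, 2000, pr$b$population)
  expect_error(judge(pr$a, shorter, small_config()), "durations differ")
  relabeled <- pr$b
  for (k in seq_along(relabeled$trains)) {
    relabeled$trains[[k]]$neuron_id <- relabeled$trains[[k]]$neuron_id + 1000L
  }
  expect_error(judge(pr$a, relabeled, small_config(measures = c("FR", "RC"))),
               "labeling")
})

test_that("comparison configs load from YAML with nested mining settings", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("measures: [FR, LV, CC]",
               "cc_bin_ms: 2",
               "n_permutations: 500",
               "seed: 3",
               "mining:",
               "  bin_width: 3",
               "  min_occurrences: 4"), path)
  cfg <- read_comparison_config(path)
  expect_s3_class(cfg, "comparison_config")
  expect_equal(cfg$measures, c("FR", "LV", "CC"))
  expect_equal(cfg$n_permutations, 500L)
  expect_equal(cfg$mining$min_occurrences, 4L)
})

test_that("the command line drives simulate, measure, compare and patterns", {
  dir <- withr::local_tempdir()
  a <- file.path(dir, "a.spk"); b <- file.path(dir, "b.spk")
  expect_equal(spikeval_cli(c("simulate", "--seed", "1", "--n-neurons", "60", "--out-degree", "20",
                              "--duration-s", "2", "--out", a)), 0L)
  expect_equal(spikeval_cli(c("simulate", "--seed", "1", "--n-neurons", "60", "--out-degree", "20",
                              "--duration-s", "2", "--out", b)), 0L)
  expect_identical(readLines(a), readLines(b))  # same seed, same output
  cfgp <- file.path(dir, "cfg.yaml")
  writeLines(c("measures: [FR, LV, ISI, RC]", "n_permutations: 200"), cfgp)
  out <- file.path(dir, "report.json")
  expect_equal(spikeval_cli(c("compare", a, b, "--config", cfgp,
                              "--out", out)), 0L)
  rep <- jsonlite::read_json(out, simplifyVector = TRUE)
  expect_equal(rep$measures$FR$effect_size$d, 0)
  mj <- file.path(dir, "dists.json")
  expect_equal(spikeval_cli(c("measure", a, "--out", mj)), 0L)
  expect_true("FR" %in% names(jsonlite::read_json(mj)))
  pj <- file.path(dir, "patterns.json")
  expect_equal(spikeval_cli(c("patterns", a, "--out", pj)), 0L)
  expect_true(file.exists(pj))
  # missing input file: exit code 2
  expect_equal(suppressMessages(
    spikeval_cli(c("compare", "nope.spk", b, "--out", out))), 2L)
  expect_equal(suppressMessages(spikeval_cli(c("bogus"))), 2L)
})
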