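test_that("network construction satisfies every connectivity invariant", {
  for (seed in c(1, 77)) {
    net <- build_network(seed = seed)
    expect_equal(net$n_neurons, 1000L)
    expect_equal(net$n_excitatory, 800L)
    expect_true(all(lengths(net$targets) == 100L))
    for (i in seq_len(net$n_neurons)) {
      tg <- net$targets[[i]]
      expect_false(any(tg == i))                       # no self-connections
      expect_equal(anyDuplicated(tg), 0L)              # no duplicate pairs
      if (i <= 800) {
        expect_true(all(net$delays[[i]] %in% 1:20))
        expect_true(all(net$weights[[i]] == 6))
      } else {
        expect_true(all(tg <= 800))                    # inhibitory -> excitatory
        expect_true(all(net$delays[[i]] == 1L))
        expect_true(all(net$weights[[i]] == -5))
      }
    }
  }
  expect_error(build_network(n_neurons = 50, out_degree = 100),
               "out_degree")
})

test_that("excitatory delays are uniform on 1..20 ms", {
  net <- build_network(seed = 5)
  d <- unlist(net$delays[1:800])
  expect_length(d, 80000L)
  expect_gt(chisq.test(table(factor(d, levels = 1:20)))$p.value, 0.001)
})

test_that("network construction is deterministic under a seed", {
  expect_identical(build_network(seed = 9), build_network(seed = 9))
  expect_false(identical(build_network(seed = 9)$targets,
                         build_network(seed = 10)$targets))
})

test_that("single-neuron dynamics: rest is silent, constant drive is tonic regular", {
  p <- neuron_params("regular_spiking")
  # from rest with no input: no spikes in 1 s
  v <- -65; u <- p$b * v
  h <- 1 / 16
  spikes <- numeric(0)
  for (step in seq_len(16000)) {
    st <- izhikevich_step(v, u, p, 0, h)
    v <- st$v; u <- st$u
    if (st$spiked) spikes <- c(spikes, step * h)
  }
  expect_length(spikes, 0L)
  # constant 10 pA: tonic spiking with near-zero LV
  v <- -65; u <- p$b * v
  spikes <- numeric(0)
  for (step in seq_len(16000)) {
    st <- izhikevich_step(v, u, p, 10, h)
    v <- st$v; u <- st$u
    if (st$spiked) spikes <- c(spikes, step * h)
  }
  expect_gt(length(spikes), 5L)
  lv <- local_coefficient_of_variation(diff(spikes))
  expect_lt(lv, 0.1)
  expect_error(izhikevich_step(NaN, u, p, 0, h), "non-finite")
})

test_that("simulation is deterministic and replays exactly from the input record", {
  net <- build_network(n_neurons = 200, out_degree = 50, seed = 2)
  r1 <- simulate_network(net, duration_s = 2, seed = 4)
  r2 <- simulate_network(net, duration_s = 2, seed = 4)
  expect_identical(lapply(r1$spikes$trains, `[[`, "spike_times"),
                   lapply(r2$spikes$trains, `[[`, "spike_times"))
  # replay through the recorded input
  r3 <- simulate_network(net, duration_s = 2, input_record = r1$input)
  expect_identical(lapply(r1$spikes$trains, `[[`, "spike_times"),
                   lapply(r3$spikes$trains, `[[`, "spike_times"))
  # different seed, different spikes
  r4 <- simulate_network(net, duration_s = 2, seed = 5)
  expect_false(identical(lapply(r1$spikes$trains, `[[`, "spike_times"),
                         lapply(r4$spikes$trains, `[[`, "spike_times")))
})

test_that("zero weights restrict spiking to directly stimulated neurons", {
  net <- build_network(n_neurons = 100, out_degree = 30, seed = 6)
  net$weights <- lapply(net$weights, function(w) w * 0)
  run <- simulate_network(net, duration_s = 2, seed = 8)
  spiking <- neuron_ids(run$spikes)[
    lengths(lapply(run$spikes$trains, `[[`, "spike_times")) > 0]
  expect_true(all(spiking %in% run$input$neuron_id))
})

test_that("default network produces plausible sustained activity", {
  set <- small_simulated_set(n_neurons = 1000, duration_s = 5, seed = 42)
  exc <- subset_population(set, "excitatory")
  fr <- mean(vapply(exc$trains, firing_rate, numeric(1)))
  expect_gt(fr, 0.5)
  expect_lt(fr, 20)
})

test_that("runaway activity aborts with a diagnostic instead of hanging", {
  net <- build_network(n_neurons = 100, out_degree = 50, w_exc = 60,
                       w_inh = 0, seed = 3)
  expect_error(simulate_network(net, duration_s = 3, seed = 1),
               "runaway activity")
})

test_that("network state files round-trip and reject corruption", {
  net <- build_network(n_neurons = 60, out_degree = 20, seed = 12)
  path <- withr::local_tempfile(fileext = ".txt")
  save_state(net, path)
  back <- load_state(path)
  expect_equal(back$targets, net$targets)
  expect_equal(back$delays, net$delays)
  expect_equal(back$weights, net$weights)
  expect_equal(back$n_excitatory, net$n_excitatory)
  writeLines("not a state file", path)
  expect_error(load_state(path), "missing header")
  save_state(net, path)
  writeLines(head(readLines(path), -5), path)
  expect_error(load_state(path), "corrupted")
})

test_that("jittered network states differ only in excitatory weights", {
  net <- build_network(n_neurons = 80, out_degree = 20, seed = 1)
  states <- network_states(net, n_states = 5, jitter_sd = 1, seed = 30)
  expect_length(states, 5L)
  for (st in states) {
    expect_identical(st$targets, net$targets)
    expect_identical(st$delays, net$delays)
    ex <- unlist(st$weights[seq_len(net$n_excitatory)])
    expect_true(all(ex >= 0 & ex <= 10))
    expect_identical(st$weights[-seq_len(net$n_excitatory)],
                     net$weights[-seq_len(net$n_excitatory)])
  }
  expect_false(identical(states[[1]]$weights, states[[2]]$weights))
})

test_that("input records round-trip as two-column text", {
  net <- build_network(n_neurons = 50, out_degree = 20, seed = 13)
  run <- simulate_network(net, duration_s = 1, seed = 14)
  path <- withr::local_tempfile(fileext = ".txt")
  write_input_record(run$input, path)
  back <- read_input_record(path)
  expect_equal(back$step, run$input$step)
  expect_equal(back$neuron_id, run$input$neuron_id)
  expect_equal(attr(back, "amplitude"), 20)
})
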