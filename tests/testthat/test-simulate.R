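test_that("class counts follow largest-remainder apportionment exactly", {
  pop <- population_spec(
    n_neurons = 100,
    class_proportions = c(il1b_specific = 0.4, tnf_specific = 0.3,
                          il10_responsive = 0.2, multi_cytokine = 0.1,
                          non_cytokine = 0),
    event_schedule = three_cytokine_events(), duration = 1000, seed = 1)
  ds <- simulate_population(pop, control_condition())
  tab <- table(ds$truth$neurons$class)
  expect_identical(as.integer(tab[c("il1b_specific", "tnf_specific",
                                    "il10_responsive", "multi_cytokine")]),
                   c(40L, 30L, 20L, 10L))
  expect_false("non_cytokine" %in% names(tab))
  # remainder ties broken by class order as listed
  pop2 <- population_spec(
    n_neurons = 3,
    class_proportions = c(il1b_specific = 0.5, tnf_specific = 0.5),
    seed = 1)
  ds2 <- simulate_population(pop2, control_condition())
  tab2 <- table(ds2$truth$neurons$class)
  expect_identical(as.integer(tab2[c("il1b_specific", "tnf_specific")]),
                   c(2L, 1L))
  expect_error(population_spec(class_proportions = c(il1b_specific = 0.7,
                                                     tnf_specific = 0.7)),
               "sum to 1")
})

test_that("simulation is deterministic for a fixed seed", {
  pop <- population_spec(n_neurons = 12, duration = 700, seed = 42)
  cond <- control_condition()
  expect_identical(simulate_population(pop, cond),
                   simulate_population(pop, cond))
  # and does not disturb the caller's RNG stream
  set.seed(7); a <- rnorm(1)
  set.seed(7); invisible(simulate_population(pop, cond)); b <- rnorm(1)
  expect_identical(a, b)
})

test_that("noise- and spontaneous-free simulation is purely evoked", {
  pop <- population_spec(
    n_neurons = 40, duration = 600, seed = 3,
    class_proportions = c(il1b_specific = 0.3, tnf_specific = 0.3,
                          il10_responsive = 0.2, multi_cytokine = 0.2,
                          non_cytokine = 0),
    event_schedule = stimulus_events(100, "TNF", 50))
  ds <- simulate_population(pop, control_condition(spont_rate = 0,
                                                   noise_sd = 0))
  truth <- ds$truth
  responders <- truth$neurons$class %in% c("tnf_specific", "multi_cytokine")
  counts <- table(factor(truth$transients$neuron_id,
                         levels = truth$neurons$neuron_id))
  expect_true(all(counts[responders] == 1L))
  expect_true(all(counts[!responders] == 0L))
  flat <- vapply(ds$traces[!responders], function(tr) max(abs(tr$dff)),
                 numeric(1))
  expect_identical(max(flat), 0)
  # every ground-truth transient lies within the recording window
  expect_true(all(truth$transients$onset >= 0 &
                    truth$transients$onset < pop$duration))
})

test_that("spontaneous transients follow the specified Poisson rate", {
  rate <- 0.3   # events/min
  n_seeds <- 200
  counts <- vapply(seq_len(n_seeds), function(s) {
    pop <- population_spec(
      n_neurons = 3, duration = 600, seed = 1000 + s,
      class_proportions = c(tnf_specific = 1),
      event_schedule = stimulus_events(numeric(0), character(0), numeric(0)))
    ds <- simulate_population(pop, control_condition(spont_rate = rate,
                                                     noise_sd = 0))
    nrow(ds$truth$transients)
  }, numeric(1))
  expected <- rate * 10 * 3            # per seed: rate * 10 min * 3 neurons
  se <- sqrt(expected * n_seeds)       # Poisson SE of the total
  expect_lt(abs(sum(counts) - expected * n_seeds), 3 * se)
})

test_that("evoked ground-truth amplitudes follow amplitude_mean * scale", {
  pop <- population_spec(
    n_neurons = 200, duration = 700, seed = 9,
    class_proportions = c(tnf_specific = 1),
    event_schedule = stimulus_events(100, "TNF", 50))
  cond <- dss_condition(spont_rate = 0)
  ds <- simulate_population(pop, cond)
  amps <- ds$truth$transients$amplitude
  target <- 56.62 * cond$evoked_amplitude_scale[["TNF"]]
  sd_target <- 9 * cond$evoked_amplitude_scale[["TNF"]]
  expect_lt(abs(mean(amps) - target), 3 * sd_target / sqrt(length(amps)))
})

test_that("guaranteed non-cytokine activity avoids assignment windows", {
  pop <- population_spec(
    n_neurons = 30, duration = 700, seed = 17,
    class_proportions = c(non_cytokine = 1))
  ds <- simulate_population(pop, control_condition(spont_rate = 0))
  tr <- ds$truth$transients
  expect_identical(nrow(tr), 30L)   # one per neuron
  for (k in seq_len(nrow(ds$events)))
    expect_false(any(tr$onset > ds$events$time_s[k] &
                       tr$onset <= ds$events$time_s[k] + pop$latency_max))
})
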