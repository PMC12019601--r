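events1 <- stimulus_events(300, "TNF", 50)

test_that("the response window is half-open at the event, closed at +100 s", {
  params <- assignment_params()
  r1 <- assign_responses(fake_transient("n1", 399, 420), events1, params)
  expect_identical(nrow(r1), 1L)
  r2 <- assign_responses(fake_transient("n1", 400, 420), events1, params)
  expect_identical(nrow(r2), 1L)      # exactly +100 s is included
  r3 <- assign_responses(fake_transient("n1", 400.05, 420), events1, params)
  expect_identical(nrow(r3), 0L)      # one sample later is not
  r4 <- assign_responses(fake_transient("n1", 300, 320), events1, params)
  expect_identical(nrow(r4), 0L)      # onset exactly at the event is excluded
})

test_that("only the earliest transient in a window is the response", {
  tr <- rbind(fake_transient("n1", 310, 330), fake_transient("n1", 350, 370))
  r <- assign_responses(tr, events1)
  expect_identical(nrow(r), 1L)
  expect_identical(r$t_onset, 310)
  expect_identical(r$latency_s, 10)
})

test_that("a transient spanning the application time suppresses the response", {
  tr <- rbind(fake_transient("n1", 290, 320), fake_transient("n1", 330, 350))
  r <- assign_responses(tr, events1)
  expect_identical(nrow(r), 0L)
  # the alternate reading is available as a config switch
  r2 <- assign_responses(tr, events1,
                         assignment_params(exclude_if_active_at_event = FALSE))
  expect_identical(nrow(r2), 1L)
  expect_identical(r2$t_onset, 330)
})

test_that("each transient answers at most one event; earlier event wins", {
  ev <- stimulus_events(c(100, 150), c("IL-1b", "TNF"), c(200, 50))
  tr <- rbind(fake_transient("n1", 160, 170), fake_transient("n1", 180, 190))
  r <- assign_responses(tr, ev)
  expect_identical(nrow(r), 2L)
  expect_identical(r$event_index, c(1L, 2L))
  expect_identical(r$t_onset, c(160, 180))
})

test_that("responder classes follow the responded-to stimulus set", {
  ev <- two_cytokine_events()
  both <- rbind(fake_transient("n1", 160, 180), fake_transient("n1", 460, 480))
  expect_identical(classify_neurons(both, ev)$class, "multi_cytokine")

  tnf_only <- fake_transient("n2", 460, 480)
  expect_identical(classify_neurons(tnf_only, ev)$class, "tnf_specific")

  outside <- fake_transient("n3", 50, 70)
  expect_identical(classify_neurons(outside, ev)$class, "non_cytokine")

  # zero-transient neurons are excluded (NA)
  cls <- classify_neurons(tnf_only, ev, neuron_ids = c("n2", "n9"))
  expect_identical(cls$class[cls$neuron_id == "n9"], NA_character_)

  ev_sal <- stimulus_events(c(150, 450), c("saline", "TNF"), c(0, 50))
  sal <- fake_transient("n4", 160, 180)
  expect_identical(classify_neurons(sal, ev_sal)$class, "saline_responder")
})

test_that("responder proportions normalise over classified neurons", {
  p <- responder_proportions(c("tnf_specific", "tnf_specific",
                               "il1b_specific", NA))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_equal(unname(p["tnf_specific"]), 2 / 3, tolerance = 1e-12)
  p2 <- responder_proportions(rep("multi_cytokine", 5))
  expect_equal(unname(p2["multi_cytokine"]), 1)
  expect_error(responder_proportions(c(NA_character_, NA_character_)), "no classified")
  p3 <- responder_proportions(c("saline_responder", "tnf_specific"),
                              exclude_saline = TRUE)
  expect_equal(unname(p3["tnf_specific"]), 1)
})

test_that("aligned averaging reproduces, averages and converges", {
  tr <- kernel_trace(onsets = c(40, 120), amplitude = 50, duration = 200)
  # single response: reproduced exactly
  one <- aligned_mean_trace(list(tr), data.frame(neuron_id = "k1",
                                                 t_onset = 40),
                            pre_s = 1, post_s = 20)
  i0 <- round(40 * 20) + 1
  expect_equal(one$mean[one$time >= 0], tr$dff[i0:(i0 + 400)],
               tolerance = 1e-12)
  # two identical segments: mean equals either, SEM = 0
  two <- aligned_mean_trace(list(tr), data.frame(neuron_id = c("k1", "k1"),
                                                 t_onset = c(40, 120)),
                            pre_s = 1, post_s = 20)
  expect_equal(two$mean, one$mean, tolerance = 1e-9)
  expect_equal(max(two$sem, na.rm = TRUE), 0, tolerance = 1e-9)
  # segments A and 3A: mean 2A, SEM = A pointwise
  trA <- kernel_trace(onsets = 40, amplitude = 20, duration = 100, id = "a")
  trB <- kernel_trace(onsets = 40, amplitude = 60, duration = 100, id = "b")
  ab <- aligned_mean_trace(list(trA, trB),
                           data.frame(neuron_id = c("a", "b"),
                                      t_onset = c(40, 40)),
                           pre_s = 0, post_s = 20)
  expect_equal(ab$mean, 2 * trA$dff[801:1201], tolerance = 1e-9)
  expect_equal(ab$sem, trA$dff[801:1201], tolerance = 1e-9)
})

test_that("the aligned mean of noisy copies converges to the kernel", {
  n <- 100
  sigma <- 2
  spec <- kernel_spec("x", 50, 0, rise_tau = 2, decay_tau = 8,
                      duration_mean = 30)
  fs <- 20
  t <- (0:(60 * fs - 1)) / fs
  kern <- render_kernel(spec, 50, t[1:(30 * fs)] - 0)
  traces <- with_seed(99, lapply(seq_len(n), function(i) {
    y <- rnorm(length(t), 0, sigma)
    y[201:(200 + length(kern))] <- y[201:(200 + length(kern))] + kern
    dff_trace(paste0("c", i), t, y)
  }))
  am <- aligned_mean_trace(traces,
                           data.frame(neuron_id = paste0("c", seq_len(n)),
                                      t_onset = 10),
                           pre_s = 0, post_s = 29.95)
  dev <- abs(am$mean - kern)
  se <- sigma / sqrt(n)
  expect_lt(mean(dev), 1.5 * se)
  expect_lt(max(dev), 4.5 * se)   # max over ~600 grid points
})

test_that("per-animal summaries average within animals and flag small n", {
  f <- data.frame(animal_id = c(rep("m1", 3), rep("m2", 10)),
                  amplitude = c(10, 20, 30, rep(5, 10)),
                  censored = FALSE)
  s <- per_animal_summary(f, "amplitude")
  expect_identical(s$mean[s$animal_id == "m1"], 20)
  expect_true(s$flagged[s$animal_id == "m1"])    # 3 < 10 traces
  expect_false(s$flagged[s$animal_id == "m2"])
  # row order is irrelevant
  s2 <- per_animal_summary(f[sample(nrow(f)), ], "amplitude")
  expect_identical(s, s2)
})

test_that("baseline activity counts neurons active before the first event", {
  tr <- rbind(fake_transient("n1", 10, 20), fake_transient("n2", 60, 70),
              fake_transient("n3", 80, 90))
  expect_identical(count_active_baseline(tr, 50), 1L)
  expect_identical(count_active_baseline(tr[0, ], 50), 0L)
  expect_error(count_active_baseline(tr, 50, stimulus_events(30, "TNF", 50)),
               "overlaps")
})

test_that("colitis-like conditions raise the baseline-active count", {
  cnt <- function(cond, seed) {
    pop <- population_spec(
      n_neurons = 80, duration = 60, seed = seed,
      class_proportions = c(tnf_specific = 1),
      event_schedule = stimulus_events(numeric(0), character(0), numeric(0)))
    count_active_baseline(detect_all(simulate_population(pop, cond)), 50)
  }
  res <- t(vapply(1:20, function(s) {
    c(ctl = cnt(control_condition(), 300 + s),
      dss = cnt(dss_condition(), 600 + s))
  }, c(ctl = 0L, dss = 0L)))
  expect_gte(mean(res[, "dss"] > res[, "ctl"]), 0.95)
})
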