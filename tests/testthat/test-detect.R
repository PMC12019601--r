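test_that("a flat trace yields no transients", {
  tr <- dff_trace("flat", (0:999) / 20, numeric(1000))
  expect_identical(nrow(detect_transients(tr)), 0L)
})

test_that("injected kernels are recovered one-to-one", {
  tr1 <- kernel_trace(onsets = 50, amplitude = 50)
  det1 <- detect_transients(tr1)
  expect_identical(nrow(det1), 1L)
  expect_equal(det1$amplitude, 50, tolerance = 1e-9)
  expect_false(det1$censored)

  tr2 <- kernel_trace(onsets = c(50, 110), amplitude = 50)
  det2 <- detect_transients(tr2)
  expect_identical(nrow(det2), 2L)
  expect_true(det2$t_onset[1] < det2$t_onset[2])
  expect_true(det2$t_offset[1] < det2$t_onset[2])   # disjoint, time-ordered
})

test_that("detected transients never overlap on noisy simulated traces", {
  pop <- population_spec(n_neurons = 15, duration = 700, seed = 21)
  ds <- simulate_population(pop, control_condition())
  feats <- detect_all(ds)
  for (id in unique(feats$neuron_id)) {
    f <- feats[feats$neuron_id == id, ]
    if (nrow(f) < 2) next
    expect_true(all(diff(f$t_onset) > 0))
    expect_true(all(f$t_offset[-nrow(f)] < f$t_onset[-1]))
    expect_true(all(f$t_onset < f$t_peak & f$t_peak <= f$t_offset))
  }
})

test_that("triangle features match the closed form exactly", {
  f <- extract_features(triangle_trace(), 0, 6)
  expect_identical(f$amplitude, 60)
  expect_identical(f$duration, 6)
  expect_identical(f$rise_slope, 30)
  expect_identical(f$decay_slope, -15)
  expect_equal(f$integral, 180, tolerance = 1e-9)   # trapezoid exact here
  expect_identical(f$n_peaks, 1L)
})

test_that("features scale with homogeneity degree 1 (or 0) in DFF", {
  tr <- kernel_trace(onsets = 50, amplitude = 40)
  tr2 <- dff_trace(tr$neuron_id, tr$time, 2 * tr$dff)
  d1 <- detect_transients(tr)
  f1 <- extract_features(tr, d1$t_onset, d1$t_offset)
  f2 <- extract_features(tr2, d1$t_onset, d1$t_offset)
  for (col in c("amplitude", "rise_slope", "decay_slope", "integral"))
    expect_equal(f2[[col]], 2 * f1[[col]], tolerance = 1e-12)
  expect_identical(f2$duration, f1$duration)
  expect_identical(f2$n_peaks, f1$n_peaks)
  expect_identical(f2$t_peak, f1$t_peak)
})

test_that("plateau peaks resolve to the first sample of the run", {
  y <- c(0, 1, 5, 5, 5, 1, 0)
  pk <- vagaltrace:::find_peaks(y)
  expect_identical(pk$index, 3L)
  expect_identical(pk$height, 5)
  # constant positive segment: one peak at the first sample, by convention
  pk2 <- vagaltrace:::find_peaks(rep(4, 6))
  expect_identical(pk2$index, 1L)
})

test_that("peak counting respects the prominence threshold", {
  t <- (0:199) / 20
  # two well-separated bumps, second at 60% amplitude
  y <- 50 * exp(-(t - 3)^2 / 0.5) + 30 * exp(-(t - 6)^2 / 0.5)
  f <- extract_features(dff_trace("b", t, y), 1, 9)
  expect_identical(f$n_peaks, 2L)
  # shallow ripple below the prominence cutoff does not count
  y2 <- 50 * exp(-(t - 3)^2 / 0.5) + 4 * exp(-(t - 6)^2 / 0.5)
  f2 <- extract_features(dff_trace("b2", t, y2), 1, 9)
  expect_identical(f2$n_peaks, 1L)
})

test_that("recording-end truncation is flagged as censored", {
  tr <- kernel_trace(onsets = 195, amplitude = 50, duration = 200)
  det <- detect_transients(tr)
  expect_identical(nrow(det), 1L)
  expect_true(det$censored)
})

test_that("traces shorter than the smoothing window are rejected", {
  tr <- dff_trace("s", (0:2) / 20, c(0, 1, 0))
  expect_error(detect_transients(tr), "smoothing window")
})

test_that("detection recall and precision are high at realistic SNR", {
  r <- recovery_run(seed = 501, n_neurons = 60)
  expect_gte(r$recall, 0.95)
  expect_gte(r$precision, 0.95)
})
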