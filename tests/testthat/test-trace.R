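test_that("trace CSV round trip preserves signal, stimuli and pacing", {
  g <- gen_transient_train(n_beats = 4, noise_sd = 0.01, seed = 2)
  p <- file.path(tempdir(), "trace.csv")
  write_trace_csv(g$trace, p)
  tr <- read_trace_csv(p)
  expect_equal(tr$signal, g$trace$signal, tolerance = 1e-12)
  expect_equal(tr$stim_times, g$trace$stim_times, tolerance = 1e-9)
  expect_equal(tr$pacing_hz, 1, tolerance = 1e-9)
  unlink(p)
})

test_that("beat segmentation yields one window per stimulus", {
  g <- gen_transient_train(n_beats = 5)
  beats <- segment_beats(g$trace)
  expect_length(beats, 5)
  expect_equal(beats[[2]]$stim_time, 1)
  expect_equal(length(beats[[1]]$signal), 1000)  # one pacing interval at 1 kHz
})

test_that("transient features recover analytic truth on an isolated beat", {
  # 0.5 Hz pacing leaves each beat fully relaxed before the next stimulus,
  # so the sampled beat matches the single-beat analytic template
  g <- gen_transient_train(amplitude = 2, pacing_hz = 0.5, n_beats = 4)
  truth <- g$ground_truth$derived_truths
  f <- transient_features(segment_beats(g$trace)[[2]])
  dt <- 1 / g$trace$fs
  expect_equal(f$amplitude, truth$amplitude, tolerance = 1e-3)
  expect_lt(abs(f$time_to_peak_s - truth$time_to_peak_s), dt)
  expect_lt(abs(f$t50_decay_s - truth$t50_decay_s), dt)
  expect_lt(abs(f$t90_decay_s - truth$t90_decay_s), dt)
  expect_equal(f$max_rise_rate, truth$max_rise_rate, tolerance = 0.05)
  expect_equal(f$max_decay_rate, truth$max_decay_rate, tolerance = 0.05)
})

test_that("features are robust to moderate noise", {
  g <- gen_transient_train(pacing_hz = 0.5, n_beats = 6, noise_sd = 0.02, seed = 9)
  truth <- g$ground_truth$derived_truths
  f <- trace_features(g$trace)
  expect_equal(median(f$amplitude), truth$amplitude, tolerance = 0.05)
  # first-crossing detection biases early under noise; allow 10%
  expect_equal(median(f$t50_decay_s), truth$t50_decay_s, tolerance = 0.1)
})

test_that("beats without a peak above the noise gate are skipped", {
  flat <- transient_trace(time_s = seq(0, 3.999, by = 0.001),
                          signal = rep(0, 4000), fs = 1000,
                          stim_times = 0:3, pacing_hz = 1)
  expect_error(transient_features(segment_beats(flat)[[1]]), "no peak")
  expect_error(suppressWarnings(trace_features(flat)), "no analysable beats")
})

test_that("numeric baseline override is honoured", {
  g <- gen_transient_train(pacing_hz = 0.5, n_beats = 3)
  b <- segment_beats(g$trace)[[2]]
  f0 <- transient_features(b)
  f1 <- transient_features(b, baseline_method = 0.1)
  expect_equal(f1$baseline, 0.1)
  expect_equal(f0$amplitude - f1$amplitude, 0.1 - f0$baseline, tolerance = 1e-9)
})

test_that("contractility normalises force to slice geometry", {
  dims <- slice_dimensions(width_mm = 5, thickness_um = 300)
  c_csa <- contractility(1.5, dims)
  expect_equal(as.numeric(c_csa), 1.5 / (5 * 0.3))
  expect_identical(attr(c_csa, "normalisation"), "csa")
  c_w <- contractility(1.5, dims, "width")
  expect_equal(as.numeric(c_w), 0.3)
  expect_error(contractility(-1, dims), "must be > 0")
})

test_that("max contractility picks the Frank-Starling optimum", {
  steps <- data.frame(stretch_level = c(0, 5, 10, 15),
                      peak_force_mN = c(0.8, 1.2, 1.5, 1.3))
  dims <- slice_dimensions(width_mm = 5)
  out <- max_contractility(steps, dims)
  expect_equal(as.numeric(out), 1.5 / (5 * 0.3))
  expect_equal(attr(out, "stretch_level"), 10)
})
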