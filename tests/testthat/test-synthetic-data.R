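test_that("every generator attaches a ground-truth record with its seed", {
  gens <- list(
    gen_transient_train(noise_sd = 0.01, seed = 3)$ground_truth,
    gen_diffraction_observation(2.0, noise_cm = 0.05, seed = 3)$ground_truth,
    gen_stretch_samples(sd = 1, seed = 3)$ground_truth,
    gen_dose_response(noise_sd = 0.02, seed = 3)$ground_truth,
    gen_mea_recording(noise_sd = 10, seed = 3)$ground_truth,
    gen_striated_image(seed = 3)$ground_truth)
  for (gt in gens) {
    expect_s3_class(gt, "ground_truth")
    expect_identical(gt$parameters$seed, 3)
  }
})

test_that("generators are bit-reproducible for a fixed seed", {
  a <- gen_transient_train(noise_sd = 0.05, seed = 11)
  b <- gen_transient_train(noise_sd = 0.05, seed = 11)
  expect_identical(a$trace$signal, b$trace$signal)
  c <- gen_transient_train(noise_sd = 0.05, seed = 12)
  expect_false(identical(a$trace$signal, c$trace$signal))

  i1 <- gen_striated_image(noise_sd = 0.05, seed = 4)
  i2 <- gen_striated_image(noise_sd = 0.05, seed = 4)
  expect_identical(i1$image, i2$image)
})

test_that("generators leave the global RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(gen_transient_train(noise_sd = 0.1, seed = 5))
  invisible(gen_mea_recording(noise_sd = 5, seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("transient train matches the stated pacing protocol", {
  g <- gen_transient_train(pacing_hz = 2, n_beats = 6)
  tr <- g$trace
  expect_length(tr$stim_times, 6)
  expect_equal(diff(tr$stim_times), rep(0.5, 5))
  expect_equal(tr$fs, 1000)
  # derived truths carry the analytic per-beat features
  expect_true(all(c("time_to_peak_s", "t50_decay_s", "t90_decay_s") %in%
                    names(g$ground_truth$derived_truths)))
})

test_that("aftercontraction events outside diastole are rejected", {
  # 0.05 s after a stimulus is during the paced contraction, not diastole
  expect_error(
    gen_transient_train(aftercontraction_spec = data.frame(time_s = 1.05,
                                                           rel_amplitude = 0.3)),
    "outside diastole")
  expect_error(
    gen_transient_train(aftercontraction_spec = data.frame(time_s = -0.1,
                                                           rel_amplitude = 0.3)),
    "precedes the first stimulus")
  # late-diastolic event is accepted and counted in the truth record
  g <- gen_transient_train(aftercontraction_spec = data.frame(time_s = 1.85,
                                                              rel_amplitude = 0.3))
  expect_equal(g$ground_truth$derived_truths$aftercontraction_count, 1L)
})

test_that("invalid time constants and noise levels are rejected", {
  expect_error(gen_transient_train(tau_rise_s = 0.3, tau_decay_s = 0.2),
               "tau_decay_s > tau_rise_s")
  expect_error(gen_transient_train(noise_sd = -1), ">= 0")
})

test_that("noise-free diffraction observation equals the analytic projection", {
  g <- diffraction_geometry()
  obs <- gen_diffraction_observation(2.2, g)
  expect_equal(obs$band_distance_cm, band_distance_from_sl(2.2, g))
  expect_equal(obs$ground_truth$derived_truths$sl_um, 2.2)
})

test_that("dose-response generator validates its concentration series", {
  expect_error(gen_dose_response(concentrations_M = c(1e-8, 1e-9)),
               "strictly increasing")
  expect_error(gen_dose_response(concentrations_M = c(-1, 1)), "positive")
  d <- gen_dose_response(ec50_M = 1e-8, hill = 1)$table
  expect_equal(d$response[d$concentration_M == 1e-8], 0.5)
})

test_that("striated-image generator respects Nyquist and pixel range", {
  expect_error(gen_striated_image(period_um = 0.15, pixel_um = 0.1), "Nyquist")
  g <- gen_striated_image(noise_sd = 0.1, seed = 2)
  expect_true(all(g$image >= 0 & g$image <= 1))
  expect_equal(dim(g$image), c(192, 192))
  expect_equal(g$ground_truth$derived_truths$period_um, 1.9)
})

test_that("MEA generator stores per-electrode activation truths", {
  g <- gen_mea_recording(cv_long = 40, cv_trans = 40)
  t_act <- g$ground_truth$derived_truths$activation_time_s
  expect_length(t_act, 60)
  el <- g$recording$layout$electrodes
  expect_equal(unname(t_act[as.character(27)]), 0)  # stim electrode
  # nearest neighbour at one pitch: 0.07 cm / 40 cm/s
  nb <- el$channel[el$row == el$row[el$channel == 27] &
                     el$col == el$col[el$channel == 27] + 1]
  expect_equal(unname(t_act[as.character(nb)]), 0.07 / 40, tolerance = 1e-12)
  expect_error(gen_mea_recording(cv_long = 10, cv_trans = 20), "cv_long >= cv_trans")
})
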