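test_that("aftercontraction rate is exact on generator output", {
  spec <- data.frame(time_s = c(1.8, 3.75, 7.8), rel_amplitude = c(0.3, 0.25, 0.4))
  g <- gen_transient_train(n_beats = 10, aftercontraction_spec = spec)
  rate <- detect_aftercontractions(g$trace)
  expect_identical(attr(rate, "count"), 3L)
  expect_equal(as.numeric(rate),
               g$ground_truth$derived_truths$aftercontraction_rate_per_min)
})

test_that("a clean paced trace has zero aftercontractions", {
  g <- gen_transient_train(n_beats = 10)
  expect_identical(attr(detect_aftercontractions(g$trace), "count"), 0L)
})

test_that("events below the prominence gate are not counted", {
  spec <- data.frame(time_s = 1.8, rel_amplitude = 0.05)  # below the 10% gate
  g <- gen_transient_train(n_beats = 10, aftercontraction_spec = spec)
  expect_identical(attr(detect_aftercontractions(g$trace), "count"), 0L)
  # but it is counted when the gate is lowered
  expect_identical(attr(detect_aftercontractions(g$trace, 0.03), "count"), 1L)
})

test_that("sustained tachyarrhythmia detection is exact on generator output", {
  g_tachy <- gen_transient_train(n_beats = 10,
                                 tachy_spec = list(onset_s = 5, rate_hz = 3))
  expect_true(detect_sustained_tachyarrhythmia(g_tachy$trace))
  g_clean <- gen_transient_train(n_beats = 10, post_stim_s = 15)
  expect_false(detect_sustained_tachyarrhythmia(g_clean$trace))
})

test_that("spontaneous rate barely above pacing is not tachyarrhythmic", {
  g <- gen_transient_train(n_beats = 10,
                           tachy_spec = list(onset_s = 5, rate_hz = 1.2))
  expect_false(detect_sustained_tachyarrhythmia(g$trace))
})

test_that("too short a post-stimulation tail is an error, not a FALSE", {
  g <- gen_transient_train(n_beats = 10, post_stim_s = 3)
  expect_error(detect_sustained_tachyarrhythmia(g$trace), "beyond stimulation stop")
})

test_that("dose-escalation assessment finds the tachyarrhythmia threshold", {
  conc <- isoproterenol_series()
  traces <- lapply(seq_along(conc), function(i) {
    if (conc[i] >= 1e-7) {
      gen_transient_train(n_beats = 10,
                          tachy_spec = list(onset_s = 6, rate_hz = 3),
                          seed = i)$trace
    } else {
      gen_transient_train(n_beats = 10, post_stim_s = 15, seed = i)$trace
    }
  })
  out <- assess_arrhythmia(traces, conc)
  expect_equal(out$threshold, 1e-7)
  expect_identical(out$score, 4L)
  expect_equal(out$rates$tachy, conc >= 1e-7)
})

test_that("a tachyarrhythmic baseline scores pre-drug", {
  conc <- isoproterenol_series()
  tachy <- gen_transient_train(n_beats = 10,
                               tachy_spec = list(onset_s = 4, rate_hz = 3))$trace
  traces <- lapply(seq_along(conc), function(i)
    gen_transient_train(n_beats = 10,
                        tachy_spec = list(onset_s = 4, rate_hz = 3),
                        seed = i)$trace)
  out <- assess_arrhythmia(traces, conc, baseline_trace = tachy)
  expect_identical(out$threshold, "pre-drug")
  expect_identical(out$score, 9L)
})

test_that("score lookup rejects off-series concentrations", {
  expect_error(arrhythmogenicity_score(2e-9), "not in the standard")
  expect_error(arrhythmogenicity_score(c(1e-9, 3e-9)), "single value")
})
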