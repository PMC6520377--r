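test_that("layout coordinates follow the grid and drop corners", {
  lay <- mea_layout()
  el <- lay$electrodes
  expect_equal(nrow(el), 60)
  expect_equal(lay$span_um, 4900)
  expect_false(any(el$row %in% c(1, 8) & el$col %in% c(1, 8)))
  expect_equal(el$channel, 0:59)
  # row-major numbering: first populated position is row 1, col 2
  expect_equal(el$x_um[1], 700)
  expect_equal(el$y_um[1], 0)
  full <- mea_layout(omit_corners = FALSE)
  expect_equal(nrow(full$electrodes), 64)
})

test_that("activation detection recovers spike times to the sample", {
  g <- gen_mea_recording(cv_long = 40, cv_trans = 40)
  rec <- g$recording
  truth <- g$ground_truth$derived_truths$activation_time_s
  map <- activation_map(rec)
  det <- map$times[map$times$flag == "detected", ]
  errs <- abs(det$time_s - unname(truth[as.character(det$channel)]))
  expect_lt(max(errs) * rec$fs, 1)  # within one sample
})

test_that("electrodes activating inside the blanking window are censored", {
  # at very high CV every electrode activates within 2 ms of the stimulus
  g <- gen_mea_recording(cv_long = 500, cv_trans = 500)
  expect_error(activation_map(g$recording), "map unusable")
})

test_that("low-SNR channels fail the detection gate", {
  g <- gen_mea_recording(cv_long = 40, cv_trans = 40, spike_amplitude_uV = 1,
                         noise_sd = 50, seed = 3)
  tr <- g$recording$traces[1, ]
  expect_true(is.na(detect_activation_time(tr, g$recording$fs, stim_time = 0.002)))
})

test_that("isotropic conduction velocity is recovered by sector regression", {
  g <- gen_mea_recording(cv_long = 50, cv_trans = 50)
  map <- activation_map(g$recording)
  cv <- conduction_velocity(map, g$recording$layout, axis_deg = 0)
  expect_equal(cv$cv_cm_s, 50, tolerance = 0.02)
  expect_gte(cv$n_electrodes_used, 4)
})

test_that("anisotropic velocities and ratio are recovered with a narrow sector", {
  g <- gen_mea_recording(cv_long = 60, cv_trans = 20)
  map <- activation_map(g$recording)
  lay <- g$recording$layout
  cvl <- conduction_velocity(map, lay, 0, sector_halfwidth_deg = 10)
  cvt <- conduction_velocity(map, lay, 90, sector_halfwidth_deg = 10)
  expect_equal(cvl$cv_cm_s, 60, tolerance = 2 / 60)
  expect_equal(cvt$cv_cm_s, 20, tolerance = 0.5 / 20)
  expect_equal(anisotropy_ratio(cvl$cv_cm_s, cvt$cv_cm_s), 3, tolerance = 0.05)
})

test_that("fiber rotation rotates the fast axis", {
  g <- gen_mea_recording(cv_long = 60, cv_trans = 20, fiber_angle_deg = 90)
  map <- activation_map(g$recording)
  lay <- g$recording$layout
  cv_y <- conduction_velocity(map, lay, 90, sector_halfwidth_deg = 10)
  cv_x <- conduction_velocity(map, lay, 0, sector_halfwidth_deg = 10)
  expect_gt(cv_y$cv_cm_s, cv_x$cv_cm_s)
  expect_equal(cv_y$cv_cm_s, 60, tolerance = 2 / 60)
})

test_that("anisotropy ratio rejects non-positive velocities", {
  expect_equal(anisotropy_ratio(60, 20), 3)
  expect_error(anisotropy_ratio(60, 0), "cv_trans")
  expect_error(anisotropy_ratio(-1, 20), "cv_long")
})

test_that("MEA recording survives a CSV + sidecar round trip", {
  g <- gen_mea_recording(cv_long = 40, cv_trans = 40, noise_sd = 5, seed = 6)
  p <- file.path(tempdir(), "rec.csv")
  write_mea_csv(g$recording, p)
  rec2 <- read_mea_csv(p)
  expect_equal(rec2$traces, g$recording$traces, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(rec2$fs, g$recording$fs)
  expect_equal(rec2$stim_channel, g$recording$stim_channel)
  expect_equal(nrow(rec2$layout$electrodes), 60)
  unlink(c(p, paste0(p, ".json")))
})

test_that("activation-map CSV export places times on the grid", {
  g <- gen_mea_recording(cv_long = 40, cv_trans = 40)
  map <- activation_map(g$recording)
  p <- file.path(tempdir(), "map.csv")
  write_activation_csv(map, g$recording$layout, p)
  m <- as.matrix(utils::read.csv(p, header = FALSE))
  expect_equal(dim(m), c(8, 8))
  expect_true(is.na(m[1, 1]))  # unpopulated corner
  unlink(p)
})
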