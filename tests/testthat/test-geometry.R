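test_that("grating equation round-trips sarcomere length and band distance", {
  g <- diffraction_geometry()
  for (sl in seq(1.7, 2.6, by = 0.1)) {
    x <- band_distance_from_sl(sl, g)
    expect_equal(sl_from_band_distance(x, g), sl, tolerance = 1e-12)
  }
  # SL 2.0 um projects ~6.84 cm on the standard rig
  expect_equal(band_distance_from_sl(2.0, g), 6.8399, tolerance = 1e-4)
})

test_that("no first-order band exists at or below the wavelength", {
  g <- diffraction_geometry()
  expect_error(band_distance_from_sl(0.633, g), "no order-1 band")
  expect_error(band_distance_from_sl(0.5, g), "no order-1 band")
  expect_error(sl_from_band_distance(0, g), "must be > 0")
})

test_that("percent stretch is engineering strain and rejects compression", {
  expect_equal(percent_stretch(10.6, 10.0), 6)
  expect_equal(percent_stretch(10.0, 10.0), 0)
  expect_error(percent_stretch(9.5, 10.0), "compression")
})

test_that("calibration fit recovers a noise-free generating line exactly", {
  s <- gen_stretch_samples(true_slope = 41.67, true_intercept = -69.26, sd = 0)
  # lm's summary warns about an essentially perfect fit on exact data
  cal <- suppressWarnings(fit_stretch_calibration(s$samples))
  expect_equal(cal$slope, 41.67, tolerance = 1e-10)
  expect_equal(cal$intercept, -69.26, tolerance = 1e-10)
  expect_equal(cal$r_squared, 1, tolerance = 1e-10)
  expect_equal(cal$n, nrow(s$samples))
})

test_that("calibration fit is consistent under noise", {
  s <- gen_stretch_samples(sd = 2, n_per_sl = 50, seed = 7)
  cal <- fit_stretch_calibration(s$samples)
  expect_equal(cal$slope, 41.67, tolerance = 0.1)
  expect_lt(cal$r_squared, 1)
})

test_that("degenerate calibration designs are rejected", {
  expect_error(fit_stretch_calibration(data.frame(sl_um = 2, percent_stretch = 5)),
               "at least 2")
  expect_error(
    fit_stretch_calibration(data.frame(sl_um = c(2, 2), percent_stretch = c(4, 5))),
    "singular")
  expect_error(fit_stretch_calibration(list(a = 1)), "data frame")
})

test_that("calibration survives a JSON round trip", {
  cal <- stretch_calibration(41.67, -69.26, r_squared = 0.4776, n = 40)
  p <- file.path(tempdir(), "cal.json")
  write_stretch_calibration(cal, p)
  cal2 <- read_stretch_calibration(p)
  expect_equal(coef(cal2), coef(cal))
  expect_equal(cal2$r_squared, 0.4776)
  expect_equal(cal2$n, 40L)
  unlink(p)
})

test_that("percent rounding is half-up to whole percent", {
  expect_identical(round_percent(5.746), 6L)
  expect_identical(round_percent(5.499), 5L)
  expect_identical(round_percent(5.5), 6L)
  expect_identical(round_percent(c(0.2, 6.5)), c(0L, 7L))
})
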