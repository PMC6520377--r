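test_that("the 4PL function hits its landmarks", {
  expect_equal(four_pl(1e-8, 0, 1, 1e-8, 1), 0.5)
  expect_equal(four_pl(1e-3, 0, 1, 1e-8, 1), 1, tolerance = 1e-4)
  expect_equal(four_pl(1e-12, 0, 1, 1e-8, 1), 0, tolerance = 1e-3)
  # steeper Hill narrows the transition
  expect_gt(four_pl(3e-8, 0, 1, 1e-8, 3), four_pl(3e-8, 0, 1, 1e-8, 1))
})

test_that("noise-free EC50 is recovered essentially exactly", {
  d <- gen_dose_response(ec50_M = 1e-8, hill = 1)$table
  fit <- fit_dose_response(d$concentration_M, d$response)
  expect_equal(log10(fit$ec50_M), -8, tolerance = 1e-6)
  expect_equal(fit$hill, 1, tolerance = 1e-4)
  expect_equal(fit$bottom, 0, tolerance = 1e-6)
  expect_equal(fit$top, 1, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
})

test_that("non-unit Hill and shifted asymptotes are recovered", {
  d <- gen_dose_response(ec50_M = 3e-8, hill = 1.8, bottom = 0.2, top = 1.4)$table
  fit <- fit_dose_response(d$concentration_M, d$response)
  expect_equal(log10(fit$ec50_M), log10(3e-8), tolerance = 1e-4)
  expect_equal(fit$hill, 1.8, tolerance = 1e-3)
  expect_equal(fit$bottom, 0.2, tolerance = 1e-4)
  expect_equal(fit$top, 1.4, tolerance = 1e-4)
})

test_that("prediction and coefficients round-trip through the fit object", {
  d <- gen_dose_response(ec50_M = 1e-8)$table
  fit <- fit_dose_response(d$concentration_M, d$response)
  expect_equal(predict(fit, d$concentration_M), d$response, tolerance = 1e-5)
  cf <- coef(fit)
  expect_named(cf, c("bottom", "top", "ec50_M", "hill"))
})

test_that("degenerate inputs are rejected with clear errors", {
  expect_error(fit_dose_response(c(1e-9, 1e-8), c(0.1, 0.9)), "at least 5")
  expect_error(fit_dose_response(1:6 * 1e-9, rep(0.5, 6)), "constant")
  expect_error(fit_dose_response(c(-1, 1, 2, 3, 4), 1:5), "positive")
  expect_error(fit_dose_response(1:5 * 1e-9, c(1, 2, NA, 4, 5)), "finite")
  expect_error(fit_dose_response(1:5 * 1e-9, 1:4), "length")
})
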