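test_that("percent positive area is exact with a fixed threshold", {
  m <- matrix(0, 10, 10)
  m[1:4, ] <- 1
  expect_equal(as.numeric(percent_positive_area(m, threshold_method = 0.5)), 40)
  # mask restricts the denominator
  msk <- matrix(FALSE, 10, 10); msk[1:5, ] <- TRUE
  expect_equal(as.numeric(percent_positive_area(m, 0.5, mask = msk)), 80)
})

test_that("Otsu separates a clearly bimodal stain", {
  g <- gen_striated_image(positive_fraction = 0.4, seed = 1)
  ppa <- percent_positive_area(calibrated_image(g$image, g$pixel_um))
  expect_equal(as.numeric(ppa), 40, tolerance = 0.1)  # relative
  expect_error(percent_positive_area(matrix(0.5, 8, 8)), "constant")
})

test_that("16-bit TIFF round trip preserves the image to quantisation", {
  g <- gen_striated_image(noise_sd = 0.05, seed = 8)
  img <- calibrated_image(g$image, g$pixel_um)
  p <- file.path(tempdir(), "img.tif")
  write_image_tiff(img, p)
  img2 <- read_image_tiff(p, pixel_um = g$pixel_um)
  expect_lt(max(abs(img2$pixels - img$pixels)), 1 / 65535)
  unlink(p)
})

test_that("t-tubule density counts stained interior fraction", {
  g <- gen_striated_image(positive_fraction = 0.4, seed = 2)
  img <- calibrated_image(g$image, g$pixel_um)
  mask <- matrix(TRUE, nrow(g$image), ncol(g$image))
  d <- ttubule_density(img, mask)
  expect_equal(as.numeric(d), 0.4, tolerance = 0.1)
})

test_that("striation regularity peaks at the generator period", {
  g <- gen_striated_image(period_um = 1.9, seed = 3)
  r <- ttubule_regularity(calibrated_image(g$image, g$pixel_um))
  # bin width at this profile length: neighbouring periods 1.745 / 2.13 um
  expect_lt(abs(1 / r$peak_period_um - 1 / 1.9), 1 / (192 * 0.1) + 1e-9)
  expect_gt(r$regularity_power, 0.5)
})

test_that("regularity power strictly decreases with phase jitter", {
  pows <- sapply(c(0, 0.1, 0.2, 0.4), function(j) {
    g <- gen_striated_image(period_um = 1.9, phase_jitter_sd_um = j, seed = 5)
    ttubule_regularity(calibrated_image(g$image, g$pixel_um))$regularity_power
  })
  expect_true(all(diff(pows) < 0))
})

test_that("morphometrics match closed forms for a rectangle and a disc", {
  m <- matrix(0L, 160, 160); m[31:130, 71:90] <- 1L
  mo <- cell_morphometrics(m, pixel_um = 0.1)
  expect_equal(mo$area_um2, 20)               # 2000 px * 0.01 um^2
  expect_equal(mo$length_width_ratio, 5, tolerance = 0.01)
  expect_equal(abs(mo$angle_deg), 90, tolerance = 1)
  xx <- outer(seq_len(121) - 61, rep(1, 121)); yy <- t(xx)
  disc <- (xx^2 + yy^2 <= 50^2) * 1L
  expect_equal(cell_morphometrics(disc, pixel_um = 0.1)$length_width_ratio, 1,
               tolerance = 0.01)
})

test_that("sub-threshold regions are excluded with a message", {
  m <- matrix(0L, 40, 40)
  m[10:20, 10:20] <- 1L   # large region
  m[30, 30] <- 2L         # 1-px region, below min_px
  expect_message(mo <- cell_morphometrics(m, pixel_um = 0.1), "excluded")
  expect_equal(nrow(mo), 1)
  expect_error(suppressMessages(cell_morphometrics(matrix(c(0L, 3L), 1, 2),
                                                   pixel_um = 0.1)),
               "size gate")
})

test_that("heterogeneity index matches the quadrant closed form", {
  q <- matrix(0, 400, 400); q[1:200, 1:200] <- 1
  h <- heterogeneity_index(q, pixel_um = 0.1, tile_um = 200 * 0.1,
                           threshold_method = 0.5)
  expect_equal(as.numeric(h), sqrt(3), tolerance = 1e-9)
  u <- matrix(rep(c(0.1, 0.9), 400 * 200), 400, 400)
  expect_lt(as.numeric(heterogeneity_index(u, pixel_um = 0.1,
                                           threshold_method = 0.5)), 0.01)
  expect_error(heterogeneity_index(q, pixel_um = 0.1, tile_um = 50), ">= 4")
})
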