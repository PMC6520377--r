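#' Calibrated 2-D intensity image
#'
#' A single-channel confocal section (or maximum projection of a z-stack)
#' with its pixel size.
#'
#' @param pixels 2-D numeric matrix of intensities.
#' @param pixel_um Pixel size (um/px), > 0.
#' @param channel Optional channel label (e.g. "cav3", "cx43").
#' @return Object of class `calibrated_image`.
#' @export
calibrated_image <- function(pixels, pixel_um, channel = NA_character_) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0)
    stopf("`pixels` must be a non-empty numeric matrix")
  assert_scalar_num(pixel_um, "pixel_um", positive = TRUE)
  structure(list(pixels = pixels, pixel_um = pixel_um, channel = channel),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("Calibrated image: %d x %d px at %g um/px%s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_um,
              if (is.na(x$channel)) "" else paste0(" [", x$channel, "]")))
  invisible(x)
}

#' Read / write a calibrated image as TIFF + JSON sidecar
#'
#' 16-bit greyscale TIFF; pixel size and channel label live in a JSON sidecar
#' (`<path>.json`) since plain TIFF carries no guaranteed calibration tag.
#' Intensities are stored scaled to [0, 1].
#'
#' @param image A [calibrated_image()] with intensities in [0, 1].
#' @param path TIFF path.
#' @param pixel_um Pixel size override when reading without a sidecar.
#' @return `write_image_tiff()` returns `path` invisibly; `read_image_tiff()`
#'   a `calibrated_image`.
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(inherits(image, "calibrated_image"))
  px <- image$pixels
  if (min(px) < 0 || max(px) > 1) stopf("intensities must be in [0, 1] for TIFF export")
  tiff::writeTIFF(px, path, bits.per.sample = 16)
  jsonlite::write_json(list(pixel_um = image$pixel_um, channel = image$channel),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path, pixel_um = NULL) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]  # first channel of multi-channel
  channel <- NA_character_
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(pixel_um)) pixel_um <- meta$pixel_um
    if (!is.null(meta$channel)) channel <- meta$channel
  }
  if (is.null(pixel_um))
    stopf("pixel size unknown: no sidecar %s and no `pixel_um` given", sidecar)
  calibrated_image(px, pixel_um, channel)
}

as_pixels <- function(image) {
  if (inherits(image, "calibrated_image")) image$pixels else image
}

# Resolve a threshold specification ("otsu" or a number) for an intensity
# vector; errors on constant input under the automatic method.
resolve_threshold <- function(values, threshold_method) {
  if (is.numeric(threshold_method)) return(threshold_method)
  if (!identical(threshold_method, "otsu"))
    stopf("threshold_method must be \"otsu\" or a numeric value")
  rng <- range(values)
  if (diff(rng) == 0)
    stopf("constant image: automatic (Otsu) threshold is undefined")
  scaled <- (values - rng[1]) / diff(rng)
  th <- EBImage::otsu(matrix(scaled, nrow = 1), range = c(0, 1))
  th * diff(rng) + rng[1]
}

#' Percent of image area above threshold
#'
#' `100 * (pixels above threshold) / (pixels considered)`.  The threshold is
#' Otsu's automatic criterion by default, or a fixed numeric value; an
#' optional mask restricts both the threshold estimation and the area
#' computation.  The threshold used is attached as an attribute.
#'
#' @param image A [calibrated_image()] or numeric matrix.
#' @param threshold_method `"otsu"` or a numeric threshold.
#' @param mask Optional logical matrix (same size) restricting the analysis.
#' @return Percent positive area (scalar, attribute `threshold`).
#' @export
percent_positive_area <- function(image, threshold_method = "otsu", mask = NULL) {
  px <- as_pixels(image)
  vals <- if (is.null(mask)) as.vector(px) else px[mask]
  if (length(vals) == 0) stopf("empty image or mask")
  th <- resolve_threshold(vals, threshold_method)
  structure(100 * mean(vals > th), threshold = th)
}

# Binary erosion of a mask by a physical margin using a disc structuring
# element.
erode_mask <- function(mask, margin_um, pixel_um) {
  r <- round(margin_um / pixel_um)
  if (r < 1) return(mask)
  kern <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  EBImage::erode(mask * 1, kern) > 0
}

#' T-tubule density within the cell interior
#'
#' Fraction of stained (above-threshold) pixels inside a cardiomyocyte,
#' after eroding the cell mask by `erode_margin_um` to exclude the surface
#' sarcolemma whose staining is not t-tubular.
#'
#' @param image Membrane-stain image ([calibrated_image()] or matrix).
#' @param cell_mask Logical or 0/1 matrix marking the cell.
#' @param pixel_um Pixel size (um/px); taken from the image when it is
#'   calibrated.
#' @param threshold_method `"otsu"` or numeric.
#' @param erode_margin_um Sarcolemma exclusion margin (um, default 1).
#' @return Positive-pixel fraction in [0, 1] (attribute `threshold`).
#' @export
ttubule_density <- function(image, cell_mask, pixel_um = NULL,
                            threshold_method = "otsu", erode_margin_um = 1) {
  px <- as_pixels(image)
  if (is.null(pixel_um) && inherits(image, "calibrated_image"))
    pixel_um <- image$pixel_um
  assert_scalar_num(pixel_um, "pixel_um", positive = TRUE)
  mask <- cell_mask > 0
  if (!any(mask & TRUE)) stopf("cell mask is empty")
  interior <- erode_mask(mask, erode_margin_um, pixel_um)
  if (!any(interior))
    stopf("erosion margin %g um leaves no cell interior", erode_margin_um)
  th <- resolve_threshold(px[mask], threshold_method)
  structure(mean(px[interior] > th), threshold = th)
}

#' Spectral regularity of a striated stain along the cell axis
#'
#' Averages intensity across the cell width into a 1-D profile along the
#' long axis (by binning pixel positions projected onto the axis at pixel
#' resolution), removes a linear trend, and computes the discrete Fourier
#' power spectrum.  The regularity power is the largest spectral peak within
#' the physiological period band divided by the total power (zero-frequency
#' term excluded), a dimensionless value in [0, 1]; the peak period is
#' reported alongside.
#'
#' @param image Stain image ([calibrated_image()] or matrix).
#' @param cell_mask Logical/0-1 matrix marking the cell; default whole image.
#' @param pixel_um Pixel size (um/px).
#' @param axis_deg Long-axis direction (degrees from +x).
#' @param period_band_um Period search band (um); the default 1.6-2.4 um
#'   brackets the physiological sarcomere spacing.
#' @return Object of class `regularity_result`: `peak_period_um`,
#'   `regularity_power`, `profile` (the detrended profile), `freq_per_um`,
#'   `power`.
#' @export
ttubule_regularity <- function(image, cell_mask = NULL, pixel_um = NULL,
                               axis_deg = 0, period_band_um = c(1.6, 2.4)) {
  px <- as_pixels(image)
  if (is.null(pixel_um) && inherits(image, "calibrated_image"))
    pixel_um <- image$pixel_um
  assert_scalar_num(pixel_um, "pixel_um", positive = TRUE)
  if (is.null(cell_mask)) cell_mask <- matrix(TRUE, nrow(px), ncol(px))
  mask <- cell_mask > 0
  th <- axis_deg * pi / 180
  nr <- nrow(px); nc <- ncol(px)
  xs <- matrix(rep((seq_len(nc) - 0.5) * pixel_um, each = nr), nr, nc)
  ys <- matrix(rep((seq_len(nr) - 0.5) * pixel_um, times = nc), nr, nc)
  u <- (xs * cos(th) + ys * sin(th))[mask]
  v <- px[mask]
  # round, not floor: u values sit at pixel centres and floor() is unstable
  # to floating-point error at exact bin edges
  bin <- round((u - min(u)) / pixel_um)
  prof <- as.numeric(tapply(v, bin, mean))
  prof <- prof[!is.na(prof)]
  n <- length(prof)
  if (n * pixel_um < 5 * max(period_band_um))
    stopf("profile spans %.3g um: need >= 5 periods of the band upper bound (%g um)",
          n * pixel_um, max(period_band_um))
  detr <- stats::resid(stats::lm(prof ~ seq_len(n)))
  pw <- Mod(stats::fft(detr))^2
  half <- 2:(floor(n / 2) + 1L)          # positive frequencies, DC excluded
  freq <- (half - 1L) / (n * pixel_um)   # cycles per um
  pw <- pw[half]
  in_band <- freq >= 1 / max(period_band_um) & freq <= 1 / min(period_band_um)
  if (!any(in_band)) stopf("no spectral bin falls in the period band")
  total <- sum(pw)
  ipk <- which(in_band)[which.max(pw[in_band])]
  structure(list(peak_period_um = 1 / freq[ipk],
                 regularity_power = if (total > 0) pw[ipk] / total else 0,
                 freq_per_um = freq, power = pw),
            class = "regularity_result")
}

#' @export
print.regularity_result <- function(x, ...) {
  cat(sprintf("Striation regularity: peak period %.3g um, regularity power %.3f\n",
              x$peak_period_um, x$regularity_power))
  invisible(x)
}

#' Per-cell morphometrics from a labelled mask
#'
#' For each labelled region: area (pixel count x pixel size squared) and the
#' length-to-width ratio from the best-fit ellipse (ratio of the square roots
#' of the principal second moments of the pixel coordinates).  Regions under
#' `min_px` pixels are excluded with a message.
#'
#' @param cell_mask Integer matrix; 0 = background, positive labels = cells.
#' @param pixel_um Pixel size (um/px).
#' @param min_px Minimum region size in pixels (default 10).
#' @return Data frame: `label`, `area_um2`, `major_um`, `minor_um`,
#'   `length_width_ratio`, `angle_deg`.
#' @export
cell_morphometrics <- function(cell_mask, pixel_um, min_px = 10) {
  assert_scalar_num(pixel_um, "pixel_um", positive = TRUE)
  labs <- sort(unique(as.vector(cell_mask)))
  labs <- labs[labs > 0]
  if (length(labs) == 0) stopf("mask has no labelled regions")
  rows <- lapply(labs, function(lb) {
    idx <- which(cell_mask == lb, arr.ind = TRUE)
    n <- nrow(idx)
    if (n < min_px) {
      message(sprintf("region %d excluded: %d px < %d", lb, n, min_px))
      return(NULL)
    }
    xy <- cbind(idx[, 2], idx[, 1]) * pixel_um      # (x, y) in um
    cm <- colMeans(xy)
    cc <- crossprod(sweep(xy, 2, cm)) / n           # second central moments
    ev <- eigen(cc, symmetric = TRUE)
    l1 <- max(ev$values[1], 0); l2 <- max(ev$values[2], 0)
    angle <- atan2(ev$vectors[2, 1], ev$vectors[1, 1]) * 180 / pi
    data.frame(label = lb, area_um2 = n * pixel_um^2,
               major_um = 4 * sqrt(l1), minor_um = 4 * sqrt(l2),
               length_width_ratio = if (l2 > 0) sqrt(l1 / l2) else Inf,
               angle_deg = angle)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("all regions were below the %d-px size gate", min_px)
  out
}

#' Spatial heterogeneity of a stain: tile-wise coefficient of variation
#'
#' The image is divided into non-overlapping square tiles of side `tile_um`;
#' a single global threshold defines positivity and the coefficient of
#' variation (population SD / mean) of the per-tile percent-positive values
#' is returned.  Uniformly distributed stain gives CV near 0; stain confined
#' to a small region gives CV above 1.
#'
#' @param image A [calibrated_image()] or matrix.
#' @param pixel_um Pixel size (um/px).
#' @param tile_um Tile side (um, default 20).
#' @param threshold_method `"otsu"` or numeric.
#' @return CV (dimensionless scalar) with attributes `n_tiles`, `threshold`.
#' @export
heterogeneity_index <- function(image, pixel_um = NULL, tile_um = 20,
                                threshold_method = "otsu") {
  px <- as_pixels(image)
  if (is.null(pixel_um) && inherits(image, "calibrated_image"))
    pixel_um <- image$pixel_um
  assert_scalar_num(pixel_um, "pixel_um", positive = TRUE)
  side <- max(1L, round(tile_um / pixel_um))
  ntr <- nrow(px) %/% side
  ntc <- ncol(px) %/% side
  if (ntr * ntc < 4)
    stopf("image spans only %d complete %g-um tiles (need >= 4)", ntr * ntc, tile_um)
  th <- resolve_threshold(as.vector(px), threshold_method)
  pos <- px > th
  tiles <- numeric(0)
  for (i in seq_len(ntr)) for (j in seq_len(ntc)) {
    block <- pos[((i - 1) * side + 1):(i * side), ((j - 1) * side + 1):(j * side)]
    tiles <- c(tiles, 100 * mean(block))
  }
  m <- mean(tiles)
  if (m == 0) stopf("no positive pixels in any tile")
  sd_pop <- sqrt(mean((tiles - m)^2))
  structure(sd_pop / m, n_tiles = length(tiles), threshold = th)
}
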