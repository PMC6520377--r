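#' Laser-diffraction measurement geometry
#'
#' The striated sarcomere lattice of a myocardial slice diffracts a laser beam
#' like a transmission grating: `d sin(theta) = m * lambda`, with `d` the
#' sarcomere length (SL).  In the measurement rig a laser is directed at the
#' slice and the diffraction pattern is projected onto a flat grid a fixed
#' distance below the tissue, so the spacing between the zero-order and
#' first-order bands on the grid encodes SL through plane trigonometry.  This
#' object holds the rig constants.
#'
#' The laser-to-slice offset plays no role in the projection formula (the
#' diffracted rays originate at the slice), so only the slice-to-grid distance
#' enters the calculation.
#'
#' @param wavelength_nm Laser wavelength in nanometres (default 633, He-Ne).
#' @param slice_to_grid_cm Distance from slice to projection grid in cm
#'   (default 20.5).
#' @param order Diffraction order used (default 1).
#' @return An object of class `diffraction_geometry`.
#' @examples
#' g <- diffraction_geometry()
#' band_distance_from_sl(2.0, g)   # ~6.84 cm
#' @export
diffraction_geometry <- function(wavelength_nm = 633,
                                 slice_to_grid_cm = 20.5,
                                 order = 1L) {
  assert_scalar_num(wavelength_nm, "wavelength_nm", positive = TRUE)
  assert_scalar_num(slice_to_grid_cm, "slice_to_grid_cm", positive = TRUE)
  assert_scalar_num(order, "order")
  if (order < 1 || order != round(order)) stopf("`order` must be an integer >= 1")
  structure(list(wavelength_nm = wavelength_nm,
                 slice_to_grid_cm = slice_to_grid_cm,
                 order = as.integer(order)),
            class = "diffraction_geometry")
}

#' @export
print.diffraction_geometry <- function(x, ...) {
  cat(sprintf("Diffraction geometry: lambda = %g nm, slice-to-grid = %g cm, order %d\n",
              x$wavelength_nm, x$slice_to_grid_cm, x$order))
  invisible(x)
}

#' Percent stretch of a mounted myocardial slice
#'
#' Engineering strain expressed in percent: `100 * (d - L0) / L0`, where `d`
#' is the distance between the stretcher posts and `L0` the resting length of
#' the slice.  Compression (`d < L0`) is not modelled and raises an error.
#'
#' @param post_distance_mm Distance between stretcher posts (mm).
#' @param resting_length_mm Resting slice length (mm).
#' @return Percent stretch (numeric scalar).
#' @examples
#' percent_stretch(10.6, 10.0)  # 6
#' @export
percent_stretch <- function(post_distance_mm, resting_length_mm) {
  assert_scalar_num(post_distance_mm, "post_distance_mm")
  assert_scalar_num(resting_length_mm, "resting_length_mm", positive = TRUE)
  if (post_distance_mm < resting_length_mm)
    stopf("post distance (%g mm) is below resting length (%g mm): compression is not modelled",
          post_distance_mm, resting_length_mm)
  100 * (post_distance_mm - resting_length_mm) / resting_length_mm
}

#' Sarcomere length from a first-order diffraction band distance
#'
#' Inverts the projection of the grating equation: with the band observed a
#' distance `x` from the zero-order band on a grid `L` below the slice,
#' `theta = atan(x / L)` and `SL = m * lambda / sin(theta)`.
#'
#' @param band_distance_cm Zero-order to first-order band spacing on the
#'   projection grid (cm).
#' @param geometry A [diffraction_geometry()].
#' @return Sarcomere length in micrometres.
#' @examples
#' sl_from_band_distance(6.84, diffraction_geometry())  # ~2.0 um
#' @export
sl_from_band_distance <- function(band_distance_cm,
                                  geometry = diffraction_geometry()) {
  assert_scalar_num(band_distance_cm, "band_distance_cm")
  if (band_distance_cm <= 0) stopf("band distance must be > 0")
  theta <- atan2(band_distance_cm, geometry$slice_to_grid_cm)
  geometry$order * nm_to_um(geometry$wavelength_nm) / sin(theta)
}

#' Diffraction band distance predicted for a sarcomere length
#'
#' Forward grating-equation projection: `x = L * tan(asin(m * lambda / SL))`.
#' Defined only for `SL > m * lambda`; at or below that bound no first-order
#' band exists.
#'
#' @param sl_um Sarcomere length (um).
#' @inheritParams sl_from_band_distance
#' @return Band distance on the projection grid (cm).
#' @export
band_distance_from_sl <- function(sl_um, geometry = diffraction_geometry()) {
  assert_scalar_num(sl_um, "sl_um", positive = TRUE)
  lam_um <- geometry$order * nm_to_um(geometry$wavelength_nm)
  if (sl_um <= lam_um)
    stopf("no order-%d band exists for SL = %g um (requires SL > %g um)",
          geometry$order, sl_um, lam_um)
  geometry$slice_to_grid_cm * tan(asin(lam_um / sl_um))
}

#' Fit the percent-stretch vs sarcomere-length calibration line
#'
#' Ordinary least squares of percent stretch on sarcomere length over slices
#' stretched to diffraction-verified SLs.  The fitted line extrapolates the
#' stretch needed for SLs too short to produce a measurable diffraction
#' pattern.
#'
#' @param samples Data frame with columns `sl_um` and `percent_stretch`.
#' @return An object of class `stretch_calibration` with elements `slope`
#'   (%/um), `intercept` (%), `r_squared`, `n`, and the underlying `lm` fit.
#' @seealso [predict_percent_stretch()], [stretch_calibration()]
#' @export
fit_stretch_calibration <- function(samples) {
  if (!is.data.frame(samples) || !all(c("sl_um", "percent_stretch") %in% names(samples)))
    stopf("`samples` must be a data frame with columns sl_um and percent_stretch")
  samples <- samples[stats::complete.cases(samples[c("sl_um", "percent_stretch")]), ]
  if (nrow(samples) < 2L) stopf("at least 2 samples are required")
  if (length(unique(samples$sl_um)) < 2L)
    stopf("all sarcomere lengths are identical: design is singular")
  fit <- stats::lm(percent_stretch ~ sl_um, data = samples)
  out <- stretch_calibration(slope = unname(stats::coef(fit)[2]),
                             intercept = unname(stats::coef(fit)[1]),
                             r_squared = summary(fit)$r.squared,
                             n = nrow(samples))
  out$fit <- fit
  out
}

#' Construct a stretch calibration from known coefficients
#'
#' @param slope Slope of the calibration line (% stretch per um SL).
#' @param intercept Intercept (% stretch).
#' @param r_squared Coefficient of determination (optional).
#' @param n Number of samples behind the line (optional).
#' @return An object of class `stretch_calibration`.
#' @examples
#' # coefficients of a published rat-slice calibration line
#' cal <- stretch_calibration(slope = 41.67, intercept = -69.26)
#' predict_percent_stretch(cal, 1.8)   # 5.746 -> reported as 6%
#' @export
stretch_calibration <- function(slope, intercept, r_squared = NA_real_, n = NA_integer_) {
  assert_scalar_num(slope, "slope")
  assert_scalar_num(intercept, "intercept")
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    stopf("r_squared must lie in [0, 1]")
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, n = n),
            class = "stretch_calibration")
}

#' @export
print.stretch_calibration <- function(x, digits = 4, ...) {
  cat("Stretch vs sarcomere-length calibration\n")
  cat(sprintf("  %% stretch = %s * SL(um) %+g\n",
              format(x$slope, digits = digits), signif(x$intercept, digits)))
  if (!is.na(x$r_squared)) cat(sprintf("  r^2 = %s", format(x$r_squared, digits = digits)))
  if (!is.na(x$n)) cat(sprintf("  (n = %d)", x$n))
  cat("\n")
  invisible(x)
}

#' @export
coef.stretch_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @rdname fit_stretch_calibration
#' @param object A `stretch_calibration`.
#' @param sl_um Sarcomere length(s) at which to predict (um).
#' @param ... Unused.
#' @export
predict.stretch_calibration <- function(object, sl_um, ...) {
  object$slope * sl_um + object$intercept
}

#' Percent stretch predicted by a calibration line
#'
#' Evaluates `slope * SL + intercept`.  Values are returned unrounded;
#' rounding to whole percent happens only at the reporting layer
#' (`round_percent()`).
#'
#' @param calibration A `stretch_calibration`.
#' @param sl_um Sarcomere length(s), um.
#' @return Percent stretch (same length as `sl_um`).
#' @export
predict_percent_stretch <- function(calibration, sl_um) {
  stopifnot(inherits(calibration, "stretch_calibration"))
  predict(calibration, sl_um)
}

#' Round a percentage for reporting
#'
#' Half-up rounding to the nearest whole percent, as used when quoting target
#' stretches.
#' @param x Percent value(s).
#' @return Integer percent.
#' @export
round_percent <- function(x) as.integer(floor(x + 0.5))

#' Persist / load a stretch calibration as JSON
#'
#' @param calibration A `stretch_calibration`.
#' @param path File path.
#' @return `write_stretch_calibration()` returns `path` invisibly;
#'   `read_stretch_calibration()` returns a `stretch_calibration`.
#' @export
write_stretch_calibration <- function(calibration, path) {
  stopifnot(inherits(calibration, "stretch_calibration"))
  jsonlite::write_json(
    list(slope = calibration$slope, intercept = calibration$intercept,
         r_squared = calibration$r_squared, n = calibration$n),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_stretch_calibration
#' @export
read_stretch_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stretch_calibration(x$slope, x$intercept,
                      r_squared = if (is.null(x$r_squared)) NA_real_ else x$r_squared,
                      n = if (is.null(x$n)) NA_integer_ else as.integer(x$n))
}
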