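#' Simulate a striated fluorescence image with known period
#'
#' Emulates a confocal field of a striated stain (t-tubules / costameres):
#' bright bands perpendicular to the given orientation, with period
#' `period_um` and duty cycle `positive_fraction` (so that fraction of the
#' area is above threshold by construction).  Optional per-stripe phase
#' jitter degrades the periodicity, and Gaussian pixel noise is added.
#' Violating the Nyquist bound (`period_um <= 2 * pixel_um`) raises an error.
#'
#' @param period_um Striation period (um).
#' @param pixel_um Pixel size (um/px).
#' @param orientation_deg Direction of the striation axis, i.e. the axis
#'   along which intensity is periodic (degrees from +x).
#' @param size_px Image size `c(rows, cols)`.
#' @param positive_fraction Duty cycle of the bright bands in (0, 1).
#' @param phase_jitter_sd_um SD of the per-stripe phase jitter (um).
#' @param noise_sd Gaussian pixel-noise SD (intensity units; image is in
#'   [0, 1]).
#' @param fg,bg Foreground / background intensity levels.
#' @param seed Integer seed.
#' @return List with `image` (matrix in [0, 1]), `pixel_um`, and
#'   `ground_truth` (period, orientation, positive fraction, jitter SD).
#' @export
gen_striated_image <- function(period_um = 1.9, pixel_um = 0.1,
                               orientation_deg = 0, size_px = c(192, 192),
                               positive_fraction = 0.4,
                               phase_jitter_sd_um = 0, noise_sd = 0.02,
                               fg = 0.9, bg = 0.1, seed = 1) {
  if (period_um <= 2 * pixel_um)
    stopf("period %g um violates Nyquist at pixel size %g um", period_um, pixel_um)
  if (positive_fraction <= 0 || positive_fraction >= 1)
    stopf("positive_fraction must be in (0, 1)")
  if (phase_jitter_sd_um < 0 || noise_sd < 0) stopf("noise parameters must be >= 0")
  nr <- size_px[1]; nc <- size_px[2]
  th <- orientation_deg * pi / 180
  x <- matrix(rep((seq_len(nc) - 0.5) * pixel_um, each = nr), nr, nc)
  y <- matrix(rep((seq_len(nr) - 0.5) * pixel_um, times = nc), nr, nc)
  u <- x * cos(th) + y * sin(th)
  img <- with_seed(seed, {
    k <- floor(u / period_um)
    ks <- sort(unique(as.integer(k)))
    jit <- stats::setNames(stats::rnorm(length(ks)), ks)  # unit jitter, scaled by sd
    ph <- (u - k * period_um + phase_jitter_sd_um * jit[as.character(k)]) %% period_um
    out <- ifelse(ph < positive_fraction * period_um, fg, bg)
    if (noise_sd > 0) out <- out + stats::rnorm(length(out), sd = noise_sd)
    matrix(out, nr, nc)
  })
  img <- pmin(pmax(img, 0), 1)
  gt <- ground_truth("gen_striated_image",
                     parameters = list(period_um = period_um, pixel_um = pixel_um,
                                       orientation_deg = orientation_deg,
                                       size_px = size_px,
                                       positive_fraction = positive_fraction,
                                       phase_jitter_sd_um = phase_jitter_sd_um,
                                       noise_sd = noise_sd, seed = seed),
                     derived_truths = list(period_um = period_um,
                                           orientation_deg = orientation_deg,
                                           positive_fraction = positive_fraction,
                                           spatial_freq_per_um = 1 / period_um))
  list(image = img, pixel_um = pixel_um, ground_truth = gt)
}
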