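#' Uniformly sampled transient trace (force or calcium)
#'
#' Container for a paced recording: a time axis, the signal, the sampling
#' rate, the stimulus times and the pacing rate.
#'
#' @param time_s Time axis (s), uniformly sampled.
#' @param signal Signal values (mN for force, dF for fluorescence).
#' @param fs Sampling rate (Hz).
#' @param stim_times Sorted stimulus times (s).
#' @param pacing_hz Pacing rate (Hz).
#' @return An object of class `transient_trace`.
#' @export
transient_trace <- function(time_s, signal, fs, stim_times, pacing_hz) {
  stopifnot(length(time_s) == length(signal))
  assert_scalar_num(fs, "fs", positive = TRUE)
  if (is.unsorted(stim_times)) stopf("stim_times must be sorted")
  dt <- diff(time_s)
  if (length(dt) && (max(dt) - min(dt)) > 1e-6 / fs)
    stopf("trace must be uniformly sampled")
  structure(list(time_s = time_s, signal = signal, fs = fs,
                 stim_times = stim_times, pacing_hz = pacing_hz),
            class = "transient_trace")
}

#' @export
print.transient_trace <- function(x, ...) {
  cat(sprintf("Transient trace: %.3g s at %g Hz, %d stimuli at %g Hz pacing\n",
              length(x$time_s) / x$fs, x$fs, length(x$stim_times), x$pacing_hz))
  invisible(x)
}

#' @export
plot.transient_trace <- function(x, ...) {
  graphics::plot(x$time_s, x$signal, type = "l", xlab = "time (s)",
                 ylab = "signal", ...)
  graphics::abline(v = x$stim_times, col = "grey70", lty = 3)
  invisible(x)
}

#' Read / write a transient trace as CSV
#'
#' The interchange format is a three-column CSV: `time_s`, `signal`,
#' `stim_flag` (1 on the sample nearest each stimulus, else 0).  The pacing
#' rate is recovered from the stimulus times on read (median inter-stimulus
#' interval).
#'
#' @param trace A [transient_trace()].
#' @param path CSV path.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   returns a `transient_trace`.
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "transient_trace"))
  flag <- integer(length(trace$time_s))
  idx <- round(trace$stim_times * trace$fs) + 1L
  idx <- idx[idx >= 1L & idx <= length(flag)]
  flag[idx] <- 1L
  utils::write.csv(data.frame(time_s = trace$time_s, signal = trace$signal,
                              stim_flag = flag),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "signal", "stim_flag") %in% names(d)))
    stopf("%s: expected columns time_s, signal, stim_flag", path)
  fs <- 1 / stats::median(diff(d$time_s))
  stim <- d$time_s[d$stim_flag == 1]
  pacing <- if (length(stim) > 1) 1 / stats::median(diff(stim)) else NA_real_
  transient_trace(d$time_s, d$signal, fs = fs, stim_times = stim,
                  pacing_hz = pacing)
}

#' Split a paced trace into per-beat windows
#'
#' One window per stimulus, from that stimulus to the next; the final beat's
#' window spans one pacing interval.
#'
#' @param trace A [transient_trace()].
#' @return List of beat windows; each is a list with `stim_time`, `time_s`
#'   (relative to the stimulus), `signal`, `fs`, and `pre` (the up-to-20-ms
#'   pre-stimulus segment used for baselines).
#' @export
segment_beats <- function(trace) {
  stopifnot(inherits(trace, "transient_trace"))
  stim <- trace$stim_times
  if (length(stim) == 0) stopf("trace has no stimuli")
  period <- 1 / trace$pacing_hz
  ends <- c(stim[-1], stim[length(stim)] + period)
  lapply(seq_along(stim), function(i) {
    in_win <- trace$time_s >= stim[i] & trace$time_s < ends[i]
    pre_win <- trace$time_s >= stim[i] - 0.020 & trace$time_s < stim[i]
    list(stim_time = stim[i],
         time_s = trace$time_s[in_win] - stim[i],
         signal = trace$signal[in_win],
         fs = trace$fs,
         pre = trace$signal[pre_win])
  })
}

#' Amplitude and kinetic features of a single beat
#'
#' Extracts the standard transient descriptors from one beat window:
#' amplitude (peak minus baseline), time to peak (from the stimulus), time to
#' 50% decay and time to 90% decay (first post-peak crossings of 50% and 10%
#' of the amplitude above baseline), and the maximal rise and decay rates
#' (extrema of a Savitzky-Golay-smoothed first derivative; the decay rate is
#' reported as a positive magnitude).
#'
#' @param beat One element of [segment_beats()].
#' @param baseline_method `"pre_stim_median"` (default; median of the <=20 ms
#'   pre-stimulus segment, falling back to the first sample of the window when
#'   no pre-stimulus data exist) or a numeric baseline value.
#' @param deriv_window_s Width of the smoothing window for the derivative (s);
#'   default 5 ms.
#' @return A one-row data frame of class `transient_features` with columns
#'   `amplitude`, `time_to_peak_s`, `t50_decay_s`, `t90_decay_s`,
#'   `max_rise_rate`, `max_decay_rate`, `baseline`.
#' @export
transient_features <- function(beat, baseline_method = "pre_stim_median",
                               deriv_window_s = 0.005) {
  y <- beat$signal
  fs <- beat$fs
  if (length(y) < 5) stopf("beat window too short")
  baseline <- if (is.numeric(baseline_method)) {
    baseline_method
  } else if (identical(baseline_method, "pre_stim_median")) {
    if (length(beat$pre)) stats::median(beat$pre) else y[1]
  } else stopf("unknown baseline_method")
  noise_sd <- if (length(beat$pre) > 3) stats::sd(beat$pre) else 0
  ipk <- which.max(y)
  amplitude <- y[ipk] - baseline
  if (amplitude <= 3 * noise_sd || amplitude <= 0)
    stopf("no peak above 3x baseline noise in beat window")
  time_to_peak <- beat$time_s[ipk]

  first_cross <- function(frac) {
    thr <- baseline + frac * amplitude
    post <- y[ipk:length(y)]
    j <- which(post <= thr)[1]
    if (is.na(j)) return(NA_real_)
    if (j == 1L) return(beat$time_s[ipk])
    # linear interpolation between the bracketing samples
    i0 <- ipk + j - 2L
    t0 <- beat$time_s[i0]; t1 <- beat$time_s[i0 + 1L]
    y0 <- y[i0]; y1 <- y[i0 + 1L]
    t0 + (thr - y0) / (y1 - y0) * (t1 - t0)
  }
  t50 <- first_cross(0.5)
  t90 <- first_cross(0.1)

  # smoothed first derivative (Savitzky-Golay, cubic)
  n <- max(5L, 2L * floor(deriv_window_s * fs / 2) + 1L)
  n <- min(n, 2L * floor((length(y) - 1) / 2) + 1L)
  dy <- if (n >= 5) {
    signal::sgolayfilt(y, p = 3, n = n, m = 1) * fs
  } else diff(c(y[1], y)) * fs
  rise_region <- seq_len(ipk)
  max_rise <- max(dy[rise_region])
  max_decay <- if (ipk < length(y)) -min(dy[ipk:length(y)]) else NA_real_

  out <- data.frame(amplitude = amplitude, time_to_peak_s = time_to_peak,
                    t50_decay_s = t50, t90_decay_s = t90,
                    max_rise_rate = max_rise, max_decay_rate = max_decay,
                    baseline = baseline)
  class(out) <- c("transient_features", class(out))
  out
}

#' Per-beat feature table for a whole trace
#'
#' Convenience wrapper: [segment_beats()] then [transient_features()] per
#' beat; beats that fail the peak gate are skipped with a warning.
#'
#' @inheritParams segment_beats
#' @inheritParams transient_features
#' @return Data frame, one row per analysable beat, with a `beat` index column.
#' @export
trace_features <- function(trace, baseline_method = "pre_stim_median",
                           deriv_window_s = 0.005) {
  beats <- segment_beats(trace)
  rows <- lapply(seq_along(beats), function(i) {
    f <- tryCatch(transient_features(beats[[i]], baseline_method, deriv_window_s),
                  error = function(e) NULL)
    if (is.null(f)) return(NULL)
    cbind(beat = i, f)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0)
    warning(sprintf("%d of %d beats failed the peak gate and were skipped",
                    skipped, length(beats)))
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no analysable beats in trace")
  out
}

#' Cross-sectional slice dimensions
#'
#' @param width_mm Slice width (mm).
#' @param length_mm Slice length (mm).
#' @param thickness_um Slice thickness (um); slices are cut at a nominal
#'   300 um.
#' @return An object of class `slice_dimensions`.
#' @export
slice_dimensions <- function(width_mm, length_mm = NA_real_, thickness_um = 300) {
  assert_scalar_num(width_mm, "width_mm", positive = TRUE)
  assert_scalar_num(thickness_um, "thickness_um", positive = TRUE)
  if (!is.na(length_mm) && length_mm <= 0) stopf("length_mm must be > 0")
  structure(list(width_mm = width_mm, length_mm = length_mm,
                 thickness_um = thickness_um),
            class = "slice_dimensions")
}

#' Contractility: peak force normalised to slice geometry
#'
#' With `normalisation = "csa"` (default) the peak force is divided by the
#' cross-sectional area, width x thickness, giving mN/mm^2.  With
#' `normalisation = "width"` it is divided by the slice width alone, giving
#' mN/mm (the convention used for long-term culture rigs that track width
#' only).  The result carries a `normalisation` attribute naming which was
#' used.
#'
#' @param peak_force_mN Peak systolic force (mN); must be > 0.
#' @param dims A [slice_dimensions()].
#' @param normalisation `"csa"` or `"width"`.
#' @return Normalised contractility (numeric scalar, attribute
#'   `normalisation`).
#' @examples
#' contractility(1.5, slice_dimensions(width_mm = 5))          # 1 mN/mm^2
#' contractility(1.5, slice_dimensions(width_mm = 5), "width") # 0.3 mN/mm
#' @export
contractility <- function(peak_force_mN, dims, normalisation = c("csa", "width")) {
  normalisation <- match.arg(normalisation)
  stopifnot(inherits(dims, "slice_dimensions"))
  if (!is.numeric(peak_force_mN) || peak_force_mN <= 0)
    stopf("peak force must be > 0")
  val <- switch(normalisation,
                csa = peak_force_mN / (dims$width_mm * dims$thickness_um * 1e-3),
                width = peak_force_mN / dims$width_mm)
  structure(val, normalisation = normalisation)
}

#' Maximum contractility over a stepwise stretch protocol
#'
#' Slices are stretched step by step until isometric force peaks
#' (Frank-Starling behaviour); the reported contractility is the normalised
#' force at the step with maximal peak force.
#'
#' @param steps Data frame with columns `stretch_level` and `peak_force_mN`.
#' @inheritParams contractility
#' @return Normalised contractility at the optimal step, with attributes
#'   `normalisation` and `stretch_level`.
#' @export
max_contractility <- function(steps, dims, normalisation = c("csa", "width")) {
  normalisation <- match.arg(normalisation)
  if (!is.data.frame(steps) || nrow(steps) == 0)
    stopf("`steps` must be a non-empty data frame")
  if (!all(c("stretch_level", "peak_force_mN") %in% names(steps)))
    stopf("`steps` needs columns stretch_level and peak_force_mN")
  i <- which.max(steps$peak_force_mN)
  out <- contractility(steps$peak_force_mN[i], dims, normalisation)
  attr(out, "stretch_level") <- steps$stretch_level[i]
  out
}
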