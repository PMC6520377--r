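#' Build a multielectrode-array grid layout
#'
#' Regular rows x cols grid with a fixed inter-electrode pitch.  The standard
#' array is 8 x 8 at 700 um pitch with the four corner positions unpopulated,
#' giving 60 electrodes over a ~4.9 x 4.9 mm recording area.  Coordinates:
#' x runs along columns, y along rows, origin at the top-left grid position;
#' channels are numbered 0-based in row-major order over populated positions.
#'
#' @param rows,cols Grid dimensions (>= 2).
#' @param pitch_um Inter-electrode distance (um).
#' @param omit_corners Drop the four corner positions (default TRUE).
#' @return An object of class `mea_layout`: list with `rows`, `cols`,
#'   `pitch_um`, `span_um` (side span, `(cols - 1) * pitch`), and an
#'   `electrodes` data frame (`channel`, `row`, `col`, `x_um`, `y_um`).
#' @examples
#' nrow(mea_layout()$electrodes)  # 60
#' @export
mea_layout <- function(rows = 8, cols = 8, pitch_um = 700, omit_corners = TRUE) {
  if (rows < 2 || cols < 2) stopf("rows and cols must be >= 2")
  assert_scalar_num(pitch_um, "pitch_um", positive = TRUE)
  g <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  g <- g[order(g$row, g$col), ]
  if (omit_corners) {
    corner <- (g$row %in% c(1, rows)) & (g$col %in% c(1, cols))
    g <- g[!corner, ]
  }
  electrodes <- data.frame(channel = seq_len(nrow(g)) - 1L,
                           row = g$row, col = g$col,
                           x_um = (g$col - 1) * pitch_um,
                           y_um = (g$row - 1) * pitch_um)
  structure(list(rows = rows, cols = cols, pitch_um = pitch_um,
                 omit_corners = omit_corners,
                 span_um = (cols - 1) * pitch_um,
                 electrodes = electrodes),
            class = "mea_layout")
}

#' @export
print.mea_layout <- function(x, ...) {
  cat(sprintf("MEA layout: %d x %d grid, pitch %g um, %d electrodes, side span %g mm\n",
              x$rows, x$cols, x$pitch_um, nrow(x$electrodes), x$span_um / 1000))
  invisible(x)
}

## Asymmetric biphasic field-potential template.  Base shape is a Gaussian
## derivative whose leading (positive) lobe is attenuated, then shifted so the
## unique global |extremum| (the dominant negative deflection) falls exactly
## at t_rel = 0.  Unit negative peak.
mea_spike_shape <- function(t_rel, sigma_s, pos_lobe = 0.5) {
  tau <- t_rel + sigma_s
  v <- -(tau / sigma_s) * exp(-(tau^2 - sigma_s^2) / (2 * sigma_s^2))
  v[v > 0] <- v[v > 0] * pos_lobe
  v
}

#' Simulate an MEA recording of a propagating activation wavefront
#'
#' Excitation spreads from the stimulation electrode as an elliptical
#' wavefront: in the fiber frame (rotated by `fiber_angle_deg`) an electrode
#' offset `(a, b)` activates at `t = sqrt((a/cv_long)^2 + (b/cv_trans)^2)`.
#' Each electrode's trace carries one biphasic spike (asymmetric
#' Gaussian-derivative, dominant negative deflection exactly at the activation
#' time), a brief stimulus artifact at the stimulus time on all channels, and
#' optional Gaussian noise.
#'
#' @param cv_long,cv_trans Conduction velocity along / across the fiber axis
#'   (cm/s); `cv_long >= cv_trans > 0`.
#' @param fiber_angle_deg Fiber axis direction (degrees from the +x/column
#'   axis).
#' @param stim_channel Stimulating electrode channel (0-based, must exist in
#'   the layout).
#' @param layout An [mea_layout()].
#' @param fs Sampling rate (Hz); the standard acquisition rate is 50 kHz.
#' @param spike_sigma_s Width parameter of the spike template (s).
#' @param spike_amplitude_uV Negative-peak amplitude (uV).
#' @param stim_times Stimulus time(s) within the trace (s).
#' @param noise_sd Gaussian noise SD (uV).
#' @param seed Integer seed.
#' @return List with `recording` (class `mea_recording`: `traces`
#'   channels x samples matrix, `fs`, `layout`, `stim_channel`, `stim_times`)
#'   and `ground_truth` (stores per-electrode activation times, the two
#'   velocities and the anisotropy ratio).
#' @export
gen_mea_recording <- function(cv_long = 50, cv_trans = 50, fiber_angle_deg = 0,
                              stim_channel = 27, layout = mea_layout(),
                              fs = 50000, spike_sigma_s = 4e-4,
                              spike_amplitude_uV = 500,
                              stim_times = 0.002, noise_sd = 0, seed = 1) {
  if (!(cv_long >= cv_trans && cv_trans > 0))
    stopf("need cv_long >= cv_trans > 0 (got %g, %g)", cv_long, cv_trans)
  assert_scalar_num(fs, "fs", positive = TRUE)
  el <- layout$electrodes
  if (!stim_channel %in% el$channel)
    stopf("stim_channel %s is not in the layout", stim_channel)
  sx <- el$x_um[el$channel == stim_channel]
  sy <- el$y_um[el$channel == stim_channel]
  phi <- fiber_angle_deg * pi / 180
  dx <- um_to_cm(el$x_um - sx)
  dy <- um_to_cm(el$y_um - sy)
  a <- dx * cos(phi) + dy * sin(phi)
  b <- -dx * sin(phi) + dy * cos(phi)
  t_act <- sqrt((a / cv_long)^2 + (b / cv_trans)^2)  # s, relative to stimulus

  period <- if (length(stim_times) > 1) min(diff(stim_times)) else Inf
  tail_s <- max(t_act) + 8 * spike_sigma_s
  if (is.finite(period) && tail_s > period)
    stopf("stimuli are too close together for the slowest activation")
  duration <- max(stim_times) + tail_s + 0.002
  n <- ceiling(duration * fs)
  tvec <- (seq_len(n) - 1L) / fs

  traces <- matrix(0, nrow = nrow(el), ncol = n)
  for (i in seq_len(nrow(el))) {
    for (st in stim_times) {
      # stimulus artifact: sharp decaying monophasic deflection, all channels
      art <- ifelse(tvec >= st & tvec < st + 0.001,
                    exp(-(tvec - st) / 1e-4), 0)
      sig <- 3 * spike_amplitude_uV * art +
        spike_amplitude_uV * mea_spike_shape(tvec - (st + t_act[i]), spike_sigma_s)
      traces[i, ] <- traces[i, ] + sig
    }
  }
  if (noise_sd > 0)
    traces <- traces + with_seed(seed, matrix(stats::rnorm(length(traces), sd = noise_sd),
                                              nrow = nrow(traces)))
  rec <- structure(list(traces = traces, fs = fs, layout = layout,
                        stim_channel = stim_channel, stim_times = stim_times),
                   class = "mea_recording")
  gt <- ground_truth("gen_mea_recording",
                     parameters = list(cv_long = cv_long, cv_trans = cv_trans,
                                       fiber_angle_deg = fiber_angle_deg,
                                       stim_channel = stim_channel, fs = fs,
                                       spike_sigma_s = spike_sigma_s,
                                       spike_amplitude_uV = spike_amplitude_uV,
                                       stim_times = stim_times,
                                       noise_sd = noise_sd, seed = seed),
                     derived_truths = list(cv_long = cv_long, cv_trans = cv_trans,
                                           anisotropy_ratio = cv_long / cv_trans,
                                           activation_time_s = stats::setNames(
                                             t_act, el$channel)))
  list(recording = rec, ground_truth = gt)
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("MEA recording: %d channels x %d samples at %g kHz, stim channel %d\n",
              nrow(x$traces), ncol(x$traces), x$fs / 1000, x$stim_channel))
  invisible(x)
}

#' Local activation time of one electrode trace
#'
#' Detects when the activation wavefront passes an electrode.  Default method
#' `"max_amplitude"`: the time of maximum absolute deviation from the window
#' median within a post-blanking search window after the stimulus (ties break
#' to the earlier sample).  `"max_downstroke"`: time of the most negative
#' first difference.  Detection is gated on signal-to-noise: if the peak
#' deviation does not exceed `snr_gate` times the window's median absolute
#' deviation, `NA` is returned.
#'
#' @param trace Numeric vector, one electrode's samples (uV).
#' @param fs Sampling rate (Hz).
#' @param stim_time Stimulus time (s from trace start).
#' @param blanking_ms Post-stimulus blanking interval excluded from the search
#'   (ms); covers the stimulus artifact.  Default 2 ms.
#' @param window_ms Search-window length after blanking (ms); default to the
#'   end of the trace.
#' @param method `"max_amplitude"` or `"max_downstroke"`.
#' @param snr_gate Peak-to-noise ratio required for a detection.
#' @return Activation time in seconds relative to `stim_time`, or `NA` when
#'   the gate fails.
#' @export
detect_activation_time <- function(trace, fs, stim_time = 0, blanking_ms = 2,
                                   window_ms = NULL,
                                   method = c("max_amplitude", "max_downstroke"),
                                   snr_gate = 5) {
  method <- match.arg(method)
  n <- length(trace)
  i0 <- floor((stim_time + blanking_ms / 1000) * fs) + 1L
  i1 <- if (is.null(window_ms)) n else floor((stim_time + (blanking_ms + window_ms) / 1000) * fs)
  if (i0 > n || i1 > n || i0 >= i1)
    stopf("search window [%d, %d] lies outside the trace (n = %d)", i0, i1, n)
  w <- trace[i0:i1]
  centred <- w - stats::median(w)
  noise <- stats::mad(centred)
  if (method == "max_amplitude") {
    dev <- abs(centred)
    ipk <- which.max(dev)
    if (dev[ipk] == 0 || dev[ipk] < snr_gate * noise) return(NA_real_)
  } else {
    d <- diff(w)
    ipk <- which.min(d) + 1L
    if (max(abs(centred)) == 0 || max(abs(centred)) < snr_gate * noise) return(NA_real_)
  }
  # a maximum on the first window sample is a censored spike (the electrode
  # activated inside the blanking interval): treat as missing
  if (ipk == 1L) return(NA_real_)
  (i0 + ipk - 2L) / fs - stim_time
}

#' Per-electrode activation map of a recording
#'
#' Runs [detect_activation_time()] on every electrode and every stimulus,
#' averaging times across stimuli.  The stimulating electrode is flagged and
#' excluded.  An error is raised when fewer than a quarter of electrodes
#' yield a detection (unusable map).
#'
#' @param recording An `mea_recording`.
#' @inheritParams detect_activation_time
#' @return Object of class `activation_map`: data frame `times` (`channel`,
#'   `time_s`, `flag` in `detected`/`missing`/`stim`), plus `stim_channel`.
#' @export
activation_map <- function(recording, blanking_ms = 2, window_ms = NULL,
                           method = c("max_amplitude", "max_downstroke"),
                           snr_gate = 5) {
  method <- match.arg(method)
  stopifnot(inherits(recording, "mea_recording"))
  el <- recording$layout$electrodes
  per_stim <- sapply(recording$stim_times, function(st) {
    apply(recording$traces, 1L, detect_activation_time, fs = recording$fs,
          stim_time = st, blanking_ms = blanking_ms, window_ms = window_ms,
          method = method, snr_gate = snr_gate)
  })
  per_stim <- matrix(per_stim, nrow = nrow(el))
  time_s <- rowMeans(per_stim)   # NA if missing under any stimulus
  flag <- ifelse(is.na(time_s), "missing", "detected")
  flag[el$channel == recording$stim_channel] <- "stim"
  time_s[flag == "stim"] <- NA_real_
  n_ok <- sum(flag == "detected")
  if (n_ok < 0.25 * nrow(el))
    stopf("only %d of %d electrodes detected: map unusable", n_ok, nrow(el))
  structure(list(times = data.frame(channel = el$channel, time_s = time_s,
                                    flag = flag),
                 stim_channel = recording$stim_channel),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("Activation map: %d detected, %d missing (stim channel %d)\n",
              sum(x$times$flag == "detected"), sum(x$times$flag == "missing"),
              x$stim_channel))
  invisible(x)
}

#' Export an activation map as a CSV grid
#'
#' Writes activation times (ms) on the full grid; unpopulated or undetected
#' positions are empty.
#' @param map An `activation_map`.
#' @param layout The matching [mea_layout()].
#' @param path Output CSV path.
#' @export
write_activation_csv <- function(map, layout, path) {
  g <- matrix(NA_real_, layout$rows, layout$cols)
  el <- layout$electrodes
  m <- merge(el, map$times, by = "channel")
  g[cbind(m$row, m$col)] <- m$time_s * 1000
  utils::write.table(g, path, sep = ",", row.names = FALSE, col.names = FALSE,
                     na = "")
  invisible(path)
}

#' Conduction velocity along one axis by sector-restricted regression
#'
#' Selects detected electrodes whose direction from the stimulation site lies
#' within `sector_halfwidth_deg` of the requested axis (folded, so both
#' propagation directions along the axis count), then fits ordinary least
#' squares of activation time on distance from the stimulation site.  The
#' velocity is the reciprocal slope.  In strongly anisotropic tissue the
#' wavefront is elliptical and off-axis electrodes in a wide sector run ahead
#' of the on-axis front, biasing the slope; use a narrow sector (~10 degrees)
#' to isolate on-axis propagation there.
#'
#' @param map An [activation_map()].
#' @param layout The matching [mea_layout()].
#' @param axis_deg Axis direction (degrees from the +x/column axis).
#' @param sector_halfwidth_deg Angular half-width of the accepted sector.
#' @param min_electrodes Minimum detected electrodes required in the sector.
#' @return Object of class `conduction_result`: `cv_cm_s`, `direction_deg`,
#'   `n_electrodes_used`, `fit_residual_s` (RMS time residual).
#' @export
conduction_velocity <- function(map, layout, axis_deg,
                                sector_halfwidth_deg = 30, min_electrodes = 4) {
  stopifnot(inherits(map, "activation_map"), inherits(layout, "mea_layout"))
  el <- merge(layout$electrodes, map$times, by = "channel")
  stim <- el[el$channel == map$stim_channel, ]
  det <- el[el$flag == "detected" & !is.na(el$time_s), ]
  dx <- um_to_cm(det$x_um - stim$x_um)
  dy <- um_to_cm(det$y_um - stim$y_um)
  theta <- atan2(dy, dx) * 180 / pi
  # fold the angular difference onto [0, 90]: axis is a line, not a ray
  dang <- abs(((theta - axis_deg + 90) %% 180) - 90)
  dist <- sqrt(dx^2 + dy^2)
  sel <- dang <= sector_halfwidth_deg & dist > 0
  if (sum(sel) < min_electrodes)
    stopf("only %d electrodes in the %g-degree sector (need >= %d)",
          sum(sel), sector_halfwidth_deg, min_electrodes)
  fit <- stats::lm(time_s ~ dist, data = data.frame(time_s = det$time_s[sel],
                                                    dist = dist[sel]))
  slope <- unname(stats::coef(fit)[2])  # s/cm
  if (!is.finite(slope) || slope <= 0)
    stopf("non-positive distance-time slope: retrograde propagation or failed capture")
  structure(list(cv_cm_s = 1 / slope, direction_deg = axis_deg,
                 n_electrodes_used = sum(sel),
                 fit_residual_s = sqrt(mean(stats::resid(fit)^2))),
            class = "conduction_result")
}

#' @export
print.conduction_result <- function(x, ...) {
  cat(sprintf("CV along %g deg: %.2f cm/s (%d electrodes, RMS residual %.3g ms)\n",
              x$direction_deg, x$cv_cm_s, x$n_electrodes_used,
              x$fit_residual_s * 1000))
  invisible(x)
}

#' Conduction-velocity anisotropy ratio
#'
#' Ratio of longitudinal to transverse conduction velocity (CV_L:CV_T), the
#' standard measure of conduction anisotropy.
#'
#' @param cv_long,cv_trans Velocities (cm/s); both must be > 0.
#' @return Dimensionless ratio.
#' @examples
#' anisotropy_ratio(60, 20)  # 3
#' @export
anisotropy_ratio <- function(cv_long, cv_trans) {
  if (!is.numeric(cv_trans) || cv_trans <= 0) stopf("cv_trans must be > 0")
  if (!is.numeric(cv_long) || cv_long <= 0) stopf("cv_long must be > 0")
  cv_long / cv_trans
}

#' Read / write an MEA recording as CSV + JSON sidecar
#'
#' The wide CSV holds one column per channel (`ch0`, `ch1`, ...) and one row
#' per sample; the JSON sidecar (`<path>.json`) carries `fs_hz`, `pitch_um`,
#' `rows`, `cols`, `omitted_corners`, `stim_channel` and `stim_times`.
#'
#' @param recording An `mea_recording`.
#' @param path CSV path; the sidecar is written next to it.
#' @return `write_mea_csv()` returns `path` invisibly; `read_mea_csv()`
#'   returns an `mea_recording`.
#' @export
write_mea_csv <- function(recording, path) {
  stopifnot(inherits(recording, "mea_recording"))
  m <- t(recording$traces)
  colnames(m) <- paste0("ch", recording$layout$electrodes$channel)
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  meta <- list(fs_hz = recording$fs,
               pitch_um = recording$layout$pitch_um,
               rows = recording$layout$rows, cols = recording$layout$cols,
               omitted_corners = recording$layout$omit_corners,
               stim_channel = recording$stim_channel,
               stim_times = recording$stim_times)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mea_csv
#' @export
read_mea_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.csv(path))
  layout <- mea_layout(meta$rows, meta$cols, meta$pitch_um, meta$omitted_corners)
  if (ncol(m) != nrow(layout$electrodes))
    stopf("%s: %d channels but layout has %d electrodes", path, ncol(m),
          nrow(layout$electrodes))
  structure(list(traces = t(m), fs = meta$fs_hz, layout = layout,
                 stim_channel = meta$stim_channel,
                 stim_times = as.numeric(meta$stim_times)),
            class = "mea_recording")
}
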