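#' Ground-truth record attached to every simulated dataset
#'
#' Each simulator returns, next to the data, a `ground_truth` object recording
#' the generator name, every generative parameter (including the seed) and the
#' analytically derived quantities the analysis stage should recover.
#'
#' @param generator_name Name of the generating function.
#' @param parameters Named list of generative parameters.
#' @param derived_truths Named list of derived true values.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(generator_name, parameters, derived_truths = list()) {
  structure(list(generator_name = generator_name,
                 parameters = parameters,
                 derived_truths = derived_truths),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth from", x$generator_name, "\n")
  cat("  parameters:", paste(names(x$parameters), collapse = ", "), "\n")
  if (length(x$derived_truths))
    cat("  derived:   ", paste(names(x$derived_truths), collapse = ", "), "\n")
  invisible(x)
}

#' Write a ground-truth record as a JSON sidecar
#' @param gt A `ground_truth`.
#' @param path Output path.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

## ---- difference-of-exponentials beat template -----------------------------

# Unit-peak beat shape b(t) = (exp(-t/td) - exp(-t/tr)) / peak, t >= 0.
# Analytic peak time: t* = tr*td/(td-tr) * log(td/tr).
beat_peak_time <- function(tau_rise_s, tau_decay_s) {
  tau_rise_s * tau_decay_s / (tau_decay_s - tau_rise_s) * log(tau_decay_s / tau_rise_s)
}

beat_shape <- function(t, tau_rise_s, tau_decay_s) {
  tp <- beat_peak_time(tau_rise_s, tau_decay_s)
  peak <- exp(-tp / tau_decay_s) - exp(-tp / tau_rise_s)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (exp(-t[pos] / tau_decay_s) - exp(-t[pos] / tau_rise_s)) / peak
  out
}

# Analytic per-beat features of amplitude * b(t): the continuous-time truths
# the sampled-trace analysis should recover.
beat_true_features <- function(amplitude, tau_rise_s, tau_decay_s) {
  tp <- beat_peak_time(tau_rise_s, tau_decay_s)
  cross <- function(frac) {
    stats::uniroot(function(t) beat_shape(t, tau_rise_s, tau_decay_s) - frac,
                   lower = tp, upper = tp + 60 * tau_decay_s, tol = 1e-12)$root
  }
  t50 <- cross(0.5)
  t90 <- cross(0.1)
  d1 <- function(t) {
    tpk <- beat_peak_time(tau_rise_s, tau_decay_s)
    peak <- exp(-tpk / tau_decay_s) - exp(-tpk / tau_rise_s)
    (-exp(-t / tau_decay_s) / tau_decay_s + exp(-t / tau_rise_s) / tau_rise_s) / peak
  }
  max_rise <- amplitude * max(d1(0), stats::optimize(d1, c(0, tp), maximum = TRUE)$objective)
  max_decay <- amplitude * -min(d1(tp), stats::optimize(d1, c(tp, t90 + 5 * tau_decay_s))$objective)
  list(amplitude = amplitude, time_to_peak_s = tp,
       t50_decay_s = t50, t90_decay_s = t90,
       max_rise_rate = max_rise, max_decay_rate = max_decay)
}

#' Simulate a paced transient train (force or calcium)
#'
#' Each paced beat follows a difference-of-exponentials template
#' `A * (exp(-t/tau_decay) - exp(-t/tau_rise))`, rescaled so the peak equals
#' `amplitude`.  Optional aftercontractions are injected as scaled copies of
#' the beat template in diastole, and an optional sustained tachyarrhythmia
#' replaces pacing-following beats with spontaneous beats at a faster rate
#' that continue after stimulation stops.
#'
#' @param amplitude Peak amplitude of the paced beat (signal units).
#' @param tau_rise_s,tau_decay_s Rise and decay time constants (s); must
#'   satisfy `tau_decay_s > tau_rise_s > 0`.
#' @param pacing_hz Pacing rate (Hz).
#' @param n_beats Number of paced stimuli.
#' @param aftercontraction_spec Optional data frame with columns `time_s`
#'   (event time from trace start) and `rel_amplitude` (fraction of the paced
#'   amplitude).  Events must fall in diastole (after 90% relaxation of their
#'   beat, before the next stimulus) or an error is raised.
#' @param tachy_spec Optional list `list(onset_s=, rate_hz=)`: from `onset_s`
#'   the slice beats spontaneously at `rate_hz`, continuing for
#'   `post_stim_s` seconds after the last stimulus.
#' @param noise_sd Gaussian noise SD (signal units).
#' @param fs Sampling rate (Hz); default 1000.
#' @param post_stim_s Recording tail after the last stimulus (s).  Defaults to
#'   one pacing interval, or 15 s when `tachy_spec` is given so sustained
#'   activity is observable.
#' @param seed Integer seed; the generator is bit-reproducible.
#' @return A list with `trace` (a [transient_trace()]) and `ground_truth`.
#' @export
gen_transient_train <- function(amplitude = 1, tau_rise_s = 0.02, tau_decay_s = 0.2,
                                pacing_hz = 1, n_beats = 10,
                                aftercontraction_spec = NULL, tachy_spec = NULL,
                                noise_sd = 0, fs = 1000, post_stim_s = NULL,
                                seed = 1) {
  assert_scalar_num(amplitude, "amplitude", positive = TRUE)
  assert_scalar_num(pacing_hz, "pacing_hz", positive = TRUE)
  assert_scalar_num(fs, "fs", positive = TRUE)
  if (!(tau_decay_s > tau_rise_s && tau_rise_s > 0))
    stopf("need tau_decay_s > tau_rise_s > 0 (got %g, %g)", tau_decay_s, tau_rise_s)
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  period <- 1 / pacing_hz
  stim_times <- (seq_len(n_beats) - 1L) * period
  stim_stop <- n_beats * period
  if (is.null(post_stim_s))
    post_stim_s <- if (is.null(tachy_spec)) 0 else 15
  duration <- stim_stop + post_stim_s
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  truth <- beat_true_features(amplitude, tau_rise_s, tau_decay_s)

  tachy_onset <- if (!is.null(tachy_spec)) tachy_spec$onset_s else Inf
  beat_times <- stim_times[stim_times < tachy_onset]
  if (!is.null(tachy_spec)) {
    assert_scalar_num(tachy_spec$rate_hz, "tachy_spec$rate_hz", positive = TRUE)
    tachy_beats <- seq(tachy_onset, duration, by = 1 / tachy_spec$rate_hz)
    beat_times <- c(beat_times, tachy_beats)
  }

  sig <- numeric(length(t))
  for (bt in beat_times)
    sig <- sig + amplitude * beat_shape(t - bt, tau_rise_s, tau_decay_s)

  ac_count <- 0L
  if (!is.null(aftercontraction_spec)) {
    ac <- as.data.frame(aftercontraction_spec)
    if (!all(c("time_s", "rel_amplitude") %in% names(ac)))
      stopf("aftercontraction_spec needs columns time_s and rel_amplitude")
    for (k in seq_len(nrow(ac))) {
      tev <- ac$time_s[k]
      i <- findInterval(tev, stim_times)
      if (i < 1L) stopf("aftercontraction at %g s precedes the first stimulus", tev)
      diastole_start <- stim_times[i] + truth$t90_decay_s
      diastole_end <- if (i < length(stim_times)) stim_times[i + 1L] else stim_stop
      if (tev < diastole_start || tev >= diastole_end)
        stopf("aftercontraction at %g s is outside diastole [%g, %g)",
              tev, diastole_start, diastole_end)
      sig <- sig + ac$rel_amplitude[k] * amplitude *
        beat_shape(t - tev, tau_rise_s, tau_decay_s)
    }
    ac_count <- nrow(ac)
  }

  if (noise_sd > 0)
    sig <- sig + with_seed(seed, stats::rnorm(length(sig), sd = noise_sd))

  trace <- transient_trace(time_s = t, signal = sig, fs = fs,
                           stim_times = stim_times, pacing_hz = pacing_hz)
  gt <- ground_truth(
    "gen_transient_train",
    parameters = list(amplitude = amplitude, tau_rise_s = tau_rise_s,
                      tau_decay_s = tau_decay_s, pacing_hz = pacing_hz,
                      n_beats = n_beats, noise_sd = noise_sd, fs = fs,
                      post_stim_s = post_stim_s, seed = seed),
    derived_truths = c(truth, list(
      n_beats = n_beats,
      aftercontraction_count = ac_count,
      aftercontraction_rate_per_min = ac_count / (stim_stop / 60),
      tachy_onset_s = if (is.finite(tachy_onset)) tachy_onset else NULL,
      tachy_rate_hz = if (!is.null(tachy_spec)) tachy_spec$rate_hz else NULL,
      stim_stop_s = stim_stop)))
  list(trace = trace, ground_truth = gt)
}

#' Simulate a laser-diffraction band-distance observation
#'
#' Forward grating-equation projection of a known sarcomere length through a
#' [diffraction_geometry()], plus zero-mean Gaussian measurement noise on the
#' projected band distance.
#'
#' @param sl_um True sarcomere length (um); must exceed the diffraction
#'   wavelength or no first-order band exists.
#' @param geometry A [diffraction_geometry()].
#' @param noise_cm SD of measurement noise on the band distance (cm).
#' @param seed Integer seed.
#' @return List with `band_distance_cm` and `ground_truth`.
#' @export
gen_diffraction_observation <- function(sl_um, geometry = diffraction_geometry(),
                                        noise_cm = 0, seed = 1) {
  if (noise_cm < 0) stopf("noise_cm must be >= 0")
  x <- band_distance_from_sl(sl_um, geometry)  # errors when sl_um <= m*lambda
  if (noise_cm > 0) x <- x + with_seed(seed, stats::rnorm(1, sd = noise_cm))
  gt <- ground_truth("gen_diffraction_observation",
                     parameters = list(sl_um = sl_um, noise_cm = noise_cm, seed = seed,
                                       wavelength_nm = geometry$wavelength_nm,
                                       slice_to_grid_cm = geometry$slice_to_grid_cm,
                                       order = geometry$order),
                     derived_truths = list(band_distance_cm = band_distance_from_sl(sl_um, geometry),
                                           sl_um = sl_um))
  list(band_distance_cm = x, ground_truth = gt)
}

#' Simulate noisy stretch-calibration samples
#'
#' Percent stretch is generated as `true_slope * SL + true_intercept` plus
#' Gaussian noise, at each requested sarcomere length.
#'
#' @param true_slope Slope of the generating line (%/um).
#' @param true_intercept Intercept (%).
#' @param sd Noise SD (%).
#' @param sls_um Sarcomere lengths sampled (um); must be non-empty.
#' @param n_per_sl Replicates per SL (>= 1).
#' @param seed Integer seed.
#' @return List with `samples` (data frame `sl_um`, `percent_stretch`) and
#'   `ground_truth`.
#' @export
gen_stretch_samples <- function(true_slope = 41.67, true_intercept = -69.26,
                                sd = 0, sls_um = seq(2.0, 2.4, by = 0.1),
                                n_per_sl = 10, seed = 1) {
  if (length(sls_um) == 0) stopf("`sls_um` must be non-empty")
  if (n_per_sl < 1) stopf("`n_per_sl` must be >= 1")
  if (sd < 0) stopf("`sd` must be >= 0")
  sl <- rep(sls_um, each = n_per_sl)
  y <- true_slope * sl + true_intercept
  if (sd > 0) y <- y + with_seed(seed, stats::rnorm(length(y), sd = sd))
  gt <- ground_truth("gen_stretch_samples",
                     parameters = list(true_slope = true_slope,
                                       true_intercept = true_intercept, sd = sd,
                                       sls_um = sls_um, n_per_sl = n_per_sl,
                                       seed = seed),
                     derived_truths = list(slope = true_slope,
                                           intercept = true_intercept))
  list(samples = data.frame(sl_um = sl, percent_stretch = y), ground_truth = gt)
}

#' Simulate a four-parameter logistic dose-response table
#'
#' `response = bottom + (top - bottom) / (1 + (ec50 / c)^hill)` plus Gaussian
#' noise, evaluated at the supplied concentrations.
#'
#' @param ec50_M True half-maximal concentration (M).
#' @param hill Hill coefficient.
#' @param bottom,top Lower and upper response asymptotes.
#' @param concentrations_M Strictly increasing positive concentrations (M);
#'   default the standard isoproterenol half-log series
#'   ([isoproterenol_series()]).
#' @param noise_sd Noise SD (response units).
#' @param seed Integer seed.
#' @return List with `table` (data frame `concentration_M`, `response`) and
#'   `ground_truth`.
#' @export
gen_dose_response <- function(ec50_M = 1e-8, hill = 1, bottom = 0, top = 1,
                              concentrations_M = isoproterenol_series(),
                              noise_sd = 0, seed = 1) {
  assert_scalar_num(ec50_M, "ec50_M", positive = TRUE)
  if (any(concentrations_M <= 0)) stopf("concentrations must be positive")
  if (is.unsorted(concentrations_M, strictly = TRUE))
    stopf("concentrations must be strictly increasing")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  resp <- four_pl(concentrations_M, bottom, top, ec50_M, hill)
  if (noise_sd > 0)
    resp <- resp + with_seed(seed, stats::rnorm(length(resp), sd = noise_sd))
  gt <- ground_truth("gen_dose_response",
                     parameters = list(ec50_M = ec50_M, hill = hill, bottom = bottom,
                                       top = top, noise_sd = noise_sd, seed = seed,
                                       concentrations_M = concentrations_M),
                     derived_truths = list(ec50_M = ec50_M, hill = hill,
                                           bottom = bottom, top = top))
  list(table = data.frame(concentration_M = concentrations_M, response = resp),
       ground_truth = gt)
}
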