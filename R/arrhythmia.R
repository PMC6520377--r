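#' Standard isoproterenol dose-escalation series
#'
#' Half-log concentration steps from 1e-9 to 3e-6 M using the 1-3 convention
#' (1, 3, 10, 30, ... rather than 10^0.5 multiples), matching how cumulative
#' beta-adrenergic challenges are labelled.
#'
#' @return Numeric vector of 8 molar concentrations, strictly increasing.
#' @export
isoproterenol_series <- function() {
  c(1e-9, 3e-9, 1e-8, 3e-8, 1e-7, 3e-7, 1e-6, 3e-6)
}

#' Linear arrhythmogenicity score from a tachyarrhythmia threshold
#'
#' Maps the isoproterenol concentration at which sustained tachyarrhythmia
#' first occurred to a 0-9 linear score: tachyarrhythmia already present
#' before drug ("pre-drug") scores 9, each half-log step up the series drops
#' the score by one, and absence of tachyarrhythmia across the full series
#' scores 0.
#'
#' @param threshold Either a concentration from [isoproterenol_series()] (M),
#'   the string `"pre-drug"`, or `NA`/`"none"` for no tachyarrhythmia.
#' @return Integer score in 0..9.
#' @examples
#' arrhythmogenicity_score(1e-9)       # 8
#' arrhythmogenicity_score("none")     # 0
#' arrhythmogenicity_score("pre-drug") # 9
#' @export
arrhythmogenicity_score <- function(threshold) {
  if (length(threshold) != 1L) stopf("`threshold` must be a single value")
  if (is.na(threshold) || identical(threshold, "none")) return(0L)
  if (identical(threshold, "pre-drug")) return(9L)
  if (!is.numeric(threshold)) stopf("`threshold` must be a concentration, 'pre-drug', 'none' or NA")
  series <- isoproterenol_series()
  i <- which(abs(log10(series) - log10(threshold)) < 1e-9)
  if (length(i) != 1L)
    stopf("threshold %g M is not in the standard concentration series", threshold)
  as.integer(9L - i)
}

#' Aftercontraction rate of a paced trace
#'
#' Counts spontaneous diastolic contraction events: local maxima occurring
#' after the paced beat has relaxed by 90% and before the next stimulus, with
#' prominence (rise above the surrounding diastolic signal) of at least
#' `prominence_fraction` times the paced-beat amplitude.  The count is
#' normalised to events per minute of paced recording.
#'
#' @param trace A [transient_trace()] with detectable paced beats.
#' @param prominence_fraction Minimum event prominence as a fraction of the
#'   paced amplitude (default 0.10).
#' @return Events per minute (numeric scalar) with attribute `count`.
#' @export
detect_aftercontractions <- function(trace, prominence_fraction = 0.10) {
  stopifnot(inherits(trace, "transient_trace"))
  beats <- segment_beats(trace)
  feats <- lapply(beats, function(b)
    tryCatch(transient_features(b), error = function(e) NULL))
  ok <- !vapply(feats, is.null, logical(1))
  if (!any(ok)) stopf("no detectable paced beats in trace")
  paced_amp <- stats::median(vapply(feats[ok], function(f) f$amplitude, numeric(1)))
  count <- 0L
  for (i in which(ok)) {
    b <- beats[[i]]
    f <- feats[[i]]
    # a beat that never relaxes to 10% (e.g. during tachyarrhythmia) has no
    # diastole to scan
    if (is.na(f$t90_decay_s)) next
    dia <- b$time_s > f$t90_decay_s
    if (sum(dia) < 3) next
    y <- b$signal[dia]
    pk <- local_maxima(y)
    for (p in pk) {
      # prominence: height above the minimum between diastole start and peak
      base <- min(y[seq_len(p)])
      if (y[p] - base >= prominence_fraction * paced_amp) count <- count + 1L
    }
  }
  dur_min <- (length(trace$stim_times) / trace$pacing_hz) / 60
  structure(count / dur_min, count = count)
}

#' Detect sustained tachyarrhythmia after stimulation stops
#'
#' Sustained tachyarrhythmia is declared when spontaneous contractions after
#' `stim_stop_time` run continuously at more than `rate_factor` times the
#' pacing rate for at least `min_duration_s` seconds.  Spontaneous events are
#' local maxima above 20% of the trace's peak-to-baseline range.
#'
#' @param trace A [transient_trace()] extending at least `min_duration_s`
#'   beyond `stim_stop_time`.
#' @param pacing_rate_hz Pacing rate during stimulation (Hz).
#' @param stim_stop_time Time stimulation stopped (s); defaults to one pacing
#'   interval after the last stimulus.
#' @param rate_factor Frequency multiple of the pacing rate that counts as
#'   tachyarrhythmic (default 1.5).
#' @param min_duration_s Minimum continuous duration (s, default 10).
#' @return Logical scalar.
#' @export
detect_sustained_tachyarrhythmia <- function(trace, pacing_rate_hz = trace$pacing_hz,
                                             stim_stop_time = NULL,
                                             rate_factor = 1.5,
                                             min_duration_s = 10) {
  stopifnot(inherits(trace, "transient_trace"))
  if (is.null(stim_stop_time))
    stim_stop_time <- max(trace$stim_times) + 1 / pacing_rate_hz
  t_end <- trace$time_s[length(trace$time_s)]
  if (t_end - stim_stop_time < min_duration_s)
    stopf("trace extends only %.3g s beyond stimulation stop (need >= %g s)",
          t_end - stim_stop_time, min_duration_s)
  post <- trace$time_s >= stim_stop_time
  y <- trace$signal[post]
  tt <- trace$time_s[post]
  thr <- min(y) + 0.2 * (max(y) - min(y))
  pk <- local_maxima(y)
  pk <- pk[y[pk] >= thr]
  if (length(pk) < 3) return(FALSE)
  times <- tt[pk]
  iv <- diff(times)
  fast <- iv < 1 / (rate_factor * pacing_rate_hz)
  # longest continuous run of fast inter-beat intervals
  r <- rle(fast)
  runs <- which(r$values)
  if (!length(runs)) return(FALSE)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- max(vapply(runs, function(k) sum(iv[starts[k]:ends[k]]), numeric(1)))
  best >= min_duration_s
}

#' Assess arrhythmogenicity over a dose-escalation experiment
#'
#' For each concentration in an escalating series, computes the
#' aftercontraction rate and tests for sustained tachyarrhythmia; the
#' threshold is the lowest concentration with sustained tachyarrhythmia (or
#' `"pre-drug"` when the baseline trace is already tachyarrhythmic, or `NA`
#' when none is).  The threshold is converted to the linear
#' [arrhythmogenicity_score()].
#'
#' @param traces Named list of [transient_trace()] objects, one per
#'   concentration, names ignored; order must match `concentrations_M`.
#' @param concentrations_M Concentrations (M) in escalation order.
#' @param baseline_trace Optional pre-drug trace.
#' @param prominence_fraction Passed to [detect_aftercontractions()].
#' @param ... Passed to [detect_sustained_tachyarrhythmia()].
#' @return Object of class `arrhythmia_assessment`: data frame `rates`
#'   (`concentration_M`, `aftercontractions_per_min`, `tachy`), plus
#'   `threshold` and `score`.
#' @export
assess_arrhythmia <- function(traces, concentrations_M = isoproterenol_series(),
                              baseline_trace = NULL,
                              prominence_fraction = 0.10, ...) {
  if (length(traces) != length(concentrations_M))
    stopf("%d traces for %d concentrations", length(traces), length(concentrations_M))
  pre_drug <- !is.null(baseline_trace) &&
    detect_sustained_tachyarrhythmia(baseline_trace, ...)
  rate <- numeric(length(traces))
  tachy <- logical(length(traces))
  for (i in seq_along(traces)) {
    rate[i] <- as.numeric(detect_aftercontractions(traces[[i]], prominence_fraction))
    tachy[i] <- detect_sustained_tachyarrhythmia(traces[[i]], ...)
  }
  threshold <- if (pre_drug) "pre-drug"
  else if (any(tachy)) concentrations_M[which(tachy)[1]]
  else NA_real_
  structure(list(rates = data.frame(concentration_M = concentrations_M,
                                    aftercontractions_per_min = rate,
                                    tachy = tachy),
                 threshold = threshold,
                 score = arrhythmogenicity_score(threshold)),
            class = "arrhythmia_assessment")
}

#' @export
print.arrhythmia_assessment <- function(x, ...) {
  thr <- if (is.numeric(x$threshold) && is.na(x$threshold)) "none"
  else format(x$threshold)
  cat(sprintf("Arrhythmia assessment: threshold = %s, score = %d\n", thr, x$score))
  print(x$rates)
  invisible(x)
}
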