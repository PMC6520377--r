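---
title: "Methods: models, defaults and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, defaults and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicephys)
```

This vignette documents the models behind each analysis stage, every default
parameter with its units and rationale, what the synthetic-data generators do
and do not emulate, and the numerical conventions the package commits to.

# Geometry: sarcomere length by laser diffraction

The sarcomere lattice diffracts a laser like a transmission grating,
`d sin(theta) = m lambda`, with `d` the sarcomere length (SL). The rig
projects the pattern onto a flat grid a distance `L` below the slice, so the
zero-to-first-order band spacing `x` satisfies `theta = atan(x / L)` and

```
SL = m * lambda / sin(atan(x / L))        (inverse)
x  = L * tan(asin(m * lambda / SL))       (forward)
```

Defaults (`diffraction_geometry()`): `lambda = 633` nm (He-Ne laser),
`L = 20.5` cm, order `m = 1`. The laser-to-slice offset does not enter: the
diffracted rays originate at the slice. At SL = 2.0 µm the first-order band
falls 6.84 cm from the zero order. No first-order band exists for
`SL <= m * lambda` (0.633 µm), and the forward projection errors there.

```{r}
g <- diffraction_geometry()
band_distance_from_sl(2.0, g)
sl_from_band_distance(6.8399, g)
```

**Stretch calibration.** Percent stretch is engineering strain,
`100 * (d - L0) / L0`; compression is not modelled. SLs near the slack length
diffract too weakly to measure, so the stretch needed to reach them is
extrapolated from an ordinary-least-squares line of percent stretch on
diffraction-verified SL (`fit_stretch_calibration()`). Predictions are kept
unrounded internally; only the reporting layer rounds, half-up, to whole
percent (`round_percent()`). With the published coefficients
(slope 41.67 %/µm, intercept −69.26 %) the line gives 5.746 % at
SL = 1.8 µm, reported as 6 %.

# Conduction: MEA activation mapping

**Layout.** `mea_layout()` builds the standard 8 × 8 grid at 700 µm pitch
with the four corners unpopulated: 60 electrodes over a 4.9 mm side span.
Channels are numbered 0-based, row-major over populated positions.

**Generator.** `gen_mea_recording()` spreads excitation from the stimulus
electrode as an elliptical wavefront: in the fibre frame (rotated by
`fiber_angle_deg`) an electrode at offset `(a, b)` activates at
`t = sqrt((a / cv_long)^2 + (b / cv_trans)^2)`. Each electrode's trace
carries one biphasic spike per stimulus plus a 1 ms stimulus artifact on all
channels. The spike template is an *asymmetric* Gaussian derivative: a pure
Gaussian derivative has two equal-magnitude lobes, so "time of maximum
absolute amplitude" would be ambiguous at ±σ; attenuating the leading
positive lobe (factor 0.5) and shifting the template makes the dominant
negative deflection the unique global extremum, placed exactly at the
prescribed activation time. Defaults: `fs = 50` kHz (the standard MEA
acquisition rate), `spike_sigma_s = 4e-4` s, amplitude 500 µV, stimulus at
2 ms.

**Detection.** `detect_activation_time()` searches after a post-stimulus
blanking interval (default 2 ms, covering the artifact) for the maximum
absolute deviation from the window median; max-downstroke is available as an
alternative. A detection must exceed `snr_gate` (default 5) times the
window's median absolute deviation, otherwise the electrode is flagged
missing. Two conventions matter here:

- *Censoring*: a maximum landing on the first post-blanking sample means the
  spike peaked inside the blanking window; the detection is censored to `NA`
  rather than reported as a boundary value, which would otherwise bias
  velocity fits at high conduction speeds.
- Maps are averaged over stimuli; a map with fewer than a quarter of
  electrodes detected raises an error rather than returning a misleading fit.

**Velocity.** `conduction_velocity()` selects detected electrodes whose
direction from the stimulus site lies within `sector_halfwidth_deg` (default
30°) of the requested axis — folded, since an axis is a line, not a ray —
and regresses activation time on the *Euclidean* distance from the stimulus
electrode; velocity is the reciprocal slope. Euclidean distance, not the
along-axis projection, is the correct regressor for a point-source wavefront:
projecting onto the axis under-estimates distance for off-axis electrodes and
biases the slope even in isotropic tissue (~3 % at 30° half-width on this
grid). With Euclidean distance the isotropic estimate is exact up to sampling
error (< 2 % noise-free, < 5 % at SNR 10, across 10–100 cm/s).

In strongly anisotropic tissue the wavefront is elliptical, and off-axis
electrodes in a wide sector genuinely run ahead of the on-axis front: with
true velocities 60/20 cm/s, a 30° sector yields ≈ 43 cm/s along the fast
axis. This is a property of the geometry, not of the implementation. For
anisotropic analyses use a narrow sector (`sector_halfwidth_deg = 10`), which
recovers 60.1 / 20.0 cm/s and an anisotropy ratio of 3.00 on the standard
grid.

# Contraction: transient analysis

Each paced beat follows a difference-of-exponentials template,
`A * (exp(-t / tau_decay) - exp(-t / tau_rise))`, peak-normalised so `A` is
the beat amplitude. Defaults: `tau_rise_s = 0.02`, `tau_decay_s = 0.2`
(physiological rat-scale transient), pacing 1 Hz (the culture pacing rate),
`fs = 1000` Hz (standard force-transducer acquisition). The generator records
analytic ground truth per beat: peak time
`t* = tr*td/(td-tr) * log(td/tr)` (51.2 ms at the defaults), the 50 % and
90 % decay times by root finding, and the extremal rise/decay rates.

Analysis conventions (`transient_features()`):

- Baseline = median of the ≤ 20 ms pre-stimulus segment; amplitude = peak
  minus baseline; a beat is rejected unless the amplitude exceeds 3× the
  pre-stimulus noise SD.
- `t50`/`t90` are the first post-peak crossings of 50 % / 10 % *remaining*
  amplitude above baseline (i.e. t90 means 90 % relaxed), linearly
  interpolated between samples.
- Rise/decay rates are extrema of a Savitzky-Golay-smoothed first derivative
  (cubic, 5 ms window). The three time features recover analytic truth within
  one sample period on noise-free input; amplitude to ~0.1 % and the
  smoothed-derivative rates to ~5 %, which is the package's stated reading of
  "feature recovery" for quantities a discrete smoothed derivative cannot pin
  to one sample.

*Pacing-tail overlap.* At 1 Hz pacing with `tau_decay = 0.2` s the previous
beat has relaxed only ~99 % at the next stimulus; the residual tail raises
the measured baseline and moves t90 ~16 ms earlier than the isolated-beat
value. That is incomplete relaxation (physiology), not an analysis artifact,
so exact-recovery tests and examples use `pacing_hz = 0.5`, where beats are
fully isolated; 1 Hz remains the default because it is the culture pacing
rate.

Contractility is peak force normalised to cross-sectional area
(width × thickness, default thickness 300 µm — the nominal slice cut), in
mN/mm²; width-only normalisation (mN/mm) is available for rigs that track
width alone.

# Arrhythmia and pharmacology

`gen_transient_train()` injects aftercontractions as scaled copies of the
beat template at stated diastolic times (events outside diastole are a
generator error, keeping the ground-truth count honest), and can switch the
train to a sustained spontaneous rhythm (`tachy_spec`) that continues for
`post_stim_s` (default 15 s when tachyarrhythmic) after pacing stops.

- `detect_aftercontractions()`: local maxima after the beat's 90 % relaxation
  and before the next stimulus, with prominence ≥ 10 % of the median paced
  amplitude, reported per minute of paced recording. Beats that never reach
  90 % relaxation (as during tachyarrhythmia) have no diastole and are
  skipped.
- `detect_sustained_tachyarrhythmia()`: spontaneous events after stimulation
  stops, at more than 1.5× the pacing rate, continuously for ≥ 10 s.
- `arrhythmogenicity_score()`: linear 0–9 lookup over the isoproterenol
  half-log series 1e-9 … 3e-6 M (1–3 convention); tachyarrhythmia before drug
  scores 9, at the lowest dose 8, one less per half-log step, and absence
  over the whole series 0.
- `fit_dose_response()`: four-parameter logistic fitted on the log10
  concentration scale (the EC50 is estimated as log10 EC50, positive by
  construction) with the Levenberg-Marquardt residual interface
  `minpack.lm::nls.lm`. The `nls`-object route (`nlsLM`) constructs a model
  frame at the converged optimum and is numerically fragile when residuals
  reach machine precision (exact simulated data), so the package calls the
  optimiser directly. Noise-free EC50 is recovered to machine precision;
  at noise SD = 5 % of range over 8 levels the median |log10 error| is
  ≈ 0.075 over 50 replicates.

# Structure: image metrics

`gen_striated_image()` draws a striped stain with period 1.9 µm (t-tubule /
sarcomere spacing) at 0.1 µm/px, 40 % duty cycle, optional per-stripe phase
jitter and Gaussian intensity noise; periods at or below 2 px violate
Nyquist and error.

- Percent positive area uses Otsu's automatic threshold by default (fixed
  numeric thresholds accepted; constant images error) and records the
  threshold used.
- T-tubule density erodes the cell mask by 1 µm (disc structuring element,
  `EBImage`) to exclude surface sarcolemma before computing the stained
  fraction.
- Striation regularity averages intensity along the projected striation axis
  (profile binned at pixel resolution — *rounded*, not floored, since pixel
  centres sit exactly on bin edges), detrends linearly, and reports the
  dominant spectral peak inside the 1.6–2.4 µm period band plus the fraction
  of total (DC-excluded) power in that peak. The profile must span ≥ 5
  periods of the band's upper bound. The peak is resolved to one spectral
  bin; power decreases strictly with phase jitter.
- Heterogeneity is the tile-wise coefficient of variation of percent positive
  area (20 µm tiles, ≥ 4 tiles) using the population (1/n) standard
  deviation, so the closed form for stain confined to one of four tiles is
  exactly `sqrt(3)`.
- Morphometrics derive each labelled cell's area and length-to-width ratio
  from the principal second moments of its pixel coordinates (ellipse
  ratio = `sqrt(lambda1 / lambda2)`); regions under 10 px are excluded with a
  message.

Images interchange as 16-bit greyscale TIFF plus a JSON sidecar carrying the
pixel size (plain TIFF has no guaranteed calibration tag); 8-bit storage
would quantise away the intensity precision the spectral metrics rely on.
MEA recordings interchange as a wide CSV (one column per channel) plus a JSON
sidecar with the acquisition metadata.

# Reporting and the study runner

`compare_groups()` runs one-way ANOVA followed by Holm-adjusted
pooled-variance pairwise t tests; all-identical observations yield a flagged
`NaN` F with p = 1 rather than an error mid-pipeline. Significance tiers are
the conventional 0.05/0.01/0.001, rendered as `*` glyphs (or `$` for
comparisons against the fresh-tissue reference). The type-I error rate is
validated at 0.03–0.07 over 1000 null simulations.

`run_pipeline()` executes trace, MEA and image stages per slice from a YAML
manifest, assembles per-slice features, condition summaries (mean ± SE) and
comparisons, and writes a report directory with no timestamps, so reruns are
byte-identical. `demo_study()` writes a full synthetic three-condition study
(fresh 0 h, unloaded culture, culture at SL 2.2 µm) whose effect directions
mirror the biology: unloaded slices get smaller, slower transients, slower
longitudinal conduction and degraded striation regularity.

# Problem sizes and reproducibility

Default problem sizes are the package's own choices, picked so the full test
suite runs in seconds on one CPU while keeping every estimate comfortably
inside its tolerance: 192 × 192 px images, 10-beat trains at 1 kHz, single
stimulus MEA recordings at 50 kHz, 50-replicate EC50 recovery, 1000-run ANOVA
null calibration. All generators take an integer seed, restore the caller's
RNG state (`set.seed` is never visible to the caller), and are
bit-reproducible for a fixed seed.

# What the simulators do not emulate

- Transient templates are noiseless difference-of-exponentials: no beat-rate
  adaptation, alternans, motion artifact or photobleaching.
- The MEA model is a kinematic wavefront: no tissue heterogeneity, wavefront
  curvature anisotropy beyond the ellipse, electrode impedance variation, or
  far-field potentials; the stimulus artifact is a stylised exponential.
- Images are binary stripes plus noise: no out-of-focus light, chromatic
  offsets or segmentation difficulty; cell masks are supplied, not computed.
- Biological effect sizes in `demo_study()` are illustrative directions, not
  fitted to any dataset.

Acceptance-facing limits worth restating: wide-sector conduction velocity is
biased under strong anisotropy (use 10°); t90 at 1 Hz pacing reflects
incomplete relaxation; derivative-based rates are smoothed estimates, not
one-sample-exact.
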