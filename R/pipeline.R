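#' Run the slice-phenotyping pipeline over a study configuration
#'
#' Executes the analysis stages named by a study configuration (trace feature
#' extraction, MEA conduction mapping, image metrics) for every slice,
#' assembles the per-slice feature table, condition summaries
#' (mean +/- standard error) and one-way ANOVA comparisons, and writes them
#' to a report directory.  Output is deterministic for a fixed configuration;
#' rerunning regenerates byte-identical feature tables.
#'
#' @param config Path to a YAML study file, or an equivalent list.  Schema:
#'   top-level `slices:` (required) is a list of entries with `id`,
#'   `condition`, and any of `trace:` (trace CSV path), `mea:` (MEA CSV path,
#'   JSON sidecar expected next to it; optional `axes: {long:, trans:}` in
#'   degrees and `sector_halfwidth_deg`), `image:` (TIFF path, percent
#'   positive area).  Optional `conditions:` declares the closed label set.
#'   Relative paths resolve against the config file's directory.
#' @param out_dir Report directory (created if needed); defaults to the
#'   config's `out:` entry.
#' @return Invisibly, a list with `features`, `summary`, `comparisons` and
#'   the report paths.  Files written: `features.csv`, `summary.csv`,
#'   `comparisons.csv`, `summary.json`, `log.txt`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  base_dir <- "."
  if (is.character(config)) {
    base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$slices) || length(config$slices) == 0)
    stopf("config lists no slices")
  if (is.null(out_dir)) out_dir <- config$out
  if (is.null(out_dir)) stopf("no output directory: pass `out_dir` or set `out:`")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- character(0)
  note <- function(...) logf <<- c(logf, sprintf(...))

  resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  declared <- config$conditions
  rows <- list()
  add <- function(id, cond, feature, value)
    rows[[length(rows) + 1L]] <<- data.frame(slice = id, condition = cond,
                                             feature = feature, value = value)

  for (s in config$slices) {
    if (is.null(s$id) || is.null(s$condition))
      stopf("every slice entry needs `id` and `condition`")
    if (!is.null(declared) && !(s$condition %in% declared))
      stopf("slice %s: condition '%s' not in the declared set", s$id, s$condition)

    if (!is.null(s$trace)) {
      p <- resolve(s$trace)
      if (!file.exists(p)) stopf("slice %s: missing trace file %s", s$id, p)
      tr <- read_trace_csv(p)
      f <- trace_features(tr)
      for (col in c("amplitude", "time_to_peak_s", "t50_decay_s", "t90_decay_s",
                    "max_rise_rate", "max_decay_rate"))
        add(s$id, s$condition, col, mean(f[[col]]))
      note("slice %s: %d beats analysed from %s", s$id, nrow(f), s$trace)
    }
    if (!is.null(s$mea)) {
      p <- resolve(s$mea)
      if (!file.exists(p)) stopf("slice %s: missing MEA file %s", s$id, p)
      rec <- read_mea_csv(p)
      map <- activation_map(rec)
      axes <- if (!is.null(s$axes)) s$axes else list(long = 0, trans = 90)
      hw <- if (!is.null(s$sector_halfwidth_deg)) s$sector_halfwidth_deg else 30
      cvl <- conduction_velocity(map, rec$layout, axes$long, hw)
      cvt <- conduction_velocity(map, rec$layout, axes$trans, hw)
      add(s$id, s$condition, "cv_long_cm_s", cvl$cv_cm_s)
      add(s$id, s$condition, "cv_trans_cm_s", cvt$cv_cm_s)
      add(s$id, s$condition, "anisotropy_ratio",
          anisotropy_ratio(cvl$cv_cm_s, cvt$cv_cm_s))
      note("slice %s: CV %0.1f / %0.1f cm/s from %s", s$id, cvl$cv_cm_s,
           cvt$cv_cm_s, s$mea)
    }
    if (!is.null(s$image)) {
      p <- resolve(s$image)
      if (!file.exists(p)) stopf("slice %s: missing image file %s", s$id, p)
      img <- read_image_tiff(p)
      add(s$id, s$condition, "percent_positive_area",
          as.numeric(percent_positive_area(img)))
      note("slice %s: image metric from %s", s$id, s$image)
    }
  }
  if (length(rows) == 0) stopf("no analysable inputs in config")
  features <- do.call(rbind, rows)
  dup <- duplicated(features[c("slice", "feature")])
  if (any(dup)) stopf("duplicate (slice, feature) rows: %s",
                      paste(unique(features$slice[dup]), collapse = ", "))

  summ <- condition_summary(features)
  comp <- list()
  for (ft in unique(features$feature)) {
    d <- features[features$feature == ft, ]
    counts <- table(d$condition)
    if (length(counts) >= 2 && all(counts >= 2)) {
      g <- tryCatch(suppressWarnings(compare_groups(features, ft)),
                    error = function(e) NULL)
      if (!is.null(g))
        comp[[length(comp) + 1L]] <- data.frame(
          feature = ft, F = g$F, df1 = g$df[1], df2 = g$df[2],
          p_value = g$p_value, marker = significance_marker(g$p_value))
    }
  }
  comparisons <- if (length(comp)) do.call(rbind, comp) else
    data.frame(feature = character(0), F = numeric(0), df1 = integer(0),
               df2 = integer(0), p_value = numeric(0), marker = character(0))

  fp <- file.path(out_dir, "features.csv")
  sp <- file.path(out_dir, "summary.csv")
  cp <- file.path(out_dir, "comparisons.csv")
  utils::write.csv(features, fp, row.names = FALSE)
  utils::write.csv(summ, sp, row.names = FALSE)
  utils::write.csv(comparisons, cp, row.names = FALSE)
  jsonlite::write_json(list(n_slices = length(config$slices),
                            n_features = nrow(features),
                            conditions = sort(unique(features$condition)),
                            files = basename(c(fp, sp, cp))),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(logf, file.path(out_dir, "log.txt"))
  invisible(list(features = features, summary = summ, comparisons = comparisons,
                 out_dir = out_dir))
}

#' Write a fully synthetic demonstration study
#'
#' Generates a small three-condition study (fresh tissue, unloaded culture,
#' and culture at the optimal preload) with per-slice calcium-transient
#' traces, MEA recordings and striated-stain images, plus the matching
#' `study.yaml`, so the whole pipeline can be exercised end to end without
#' laboratory data.  Condition effects mirror the qualitative biology:
#' unloaded slices get smaller, slower transients, slower longitudinal
#' conduction and degraded striation regularity.
#'
#' @param dir Target directory (created).
#' @param seed Base seed; per-slice seeds derive from it.
#' @param n_per_condition Slices per condition (default 3).
#' @param n_beats Paced beats per trace (default 6).
#' @return Path to the written `study.yaml`, invisibly.
#' @export
demo_study <- function(dir, seed = 1, n_per_condition = 3, n_beats = 6) {
  dir.create(file.path(dir, "data"), showWarnings = FALSE, recursive = TRUE)
  conditions <- data.frame(
    name = c("0h", "unloaded", "SL2.2"),
    amplitude = c(1.0, 0.55, 0.95),
    tau_decay = c(0.20, 0.28, 0.20),
    cv_long = c(45, 30, 44),
    cv_trans = c(15, 15, 15),
    jitter = c(0.05, 0.35, 0.08))
  slices <- list()
  k <- 0L
  for (ci in seq_len(nrow(conditions))) {
    cd <- conditions[ci, ]
    for (r in seq_len(n_per_condition)) {
      k <- k + 1L
      sseed <- seed * 1000L + k
      id <- sprintf("%s_%d", gsub("\\.", "", cd$name), r)
      tr <- gen_transient_train(amplitude = cd$amplitude * (1 + 0.03 * (r - 2)),
                                tau_decay_s = cd$tau_decay, n_beats = n_beats,
                                noise_sd = 0.01, seed = sseed)$trace
      tpath <- file.path("data", paste0(id, "_trace.csv"))
      write_trace_csv(tr, file.path(dir, tpath))
      rec <- gen_mea_recording(cv_long = cd$cv_long * (1 + 0.02 * (r - 2)),
                               cv_trans = cd$cv_trans, noise_sd = 5,
                               seed = sseed)$recording
      mpath <- file.path("data", paste0(id, "_mea.csv"))
      write_mea_csv(rec, file.path(dir, mpath))
      im <- gen_striated_image(phase_jitter_sd_um = cd$jitter,
                               size_px = c(128, 128), seed = sseed)
      ipath <- file.path("data", paste0(id, "_cav3.tif"))
      write_image_tiff(calibrated_image(im$image, im$pixel_um, "cav3"),
                       file.path(dir, ipath))
      slices[[k]] <- list(id = id, condition = cd$name, trace = tpath,
                          mea = mpath, axes = list(long = 0, trans = 90),
                          sector_halfwidth_deg = 10, image = ipath)
    }
  }
  cfg <- list(seed = seed, conditions = conditions$name, out = "report",
              slices = slices)
  path <- file.path(dir, "study.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}
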