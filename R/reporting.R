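#' One-way ANOVA with Holm-adjusted pairwise comparisons
#'
#' Compares one measured feature across condition groups by one-way analysis
#' of variance, followed by pairwise pooled-variance t tests with Holm
#' adjustment.  Significance tiers use the conventional 0.05 / 0.01 / 0.001
#' cut-offs; [significance_marker()] renders them.  When every observation is
#' identical the F statistic is undefined: the comparison is flagged
#' `zero_variance` and p is reported as 1 with a warning.
#'
#' @param table Data frame with (at least) columns `condition`, `feature`,
#'   `value`.
#' @param feature Feature name to compare (a value of the `feature` column).
#' @return Object of class `group_comparison`: `feature`, `F`, `df`,
#'   `p_value`, `pairwise` (matrix of Holm-adjusted p values),
#'   `group_means`, `zero_variance`.
#' @export
compare_groups <- function(table, feature) {
  stopifnot(is.data.frame(table),
            all(c("condition", "feature", "value") %in% names(table)))
  d <- table[table$feature == feature & is.finite(table$value), ]
  if (nrow(d) == 0) stopf("no observations for feature '%s'", feature)
  d$condition <- factor(d$condition)
  counts <- table(d$condition)
  if (length(counts) < 2) stopf("need >= 2 groups (got %d)", length(counts))
  if (any(counts < 2))
    stopf("group(s) with fewer than 2 observations: %s",
          paste(names(counts)[counts < 2], collapse = ", "))
  if (stats::var(d$value) == 0) {
    warning(sprintf("feature '%s': all values identical; F undefined", feature))
    return(structure(list(feature = feature, F = NaN,
                          df = c(length(counts) - 1L, nrow(d) - length(counts)),
                          p_value = 1, pairwise = NULL,
                          group_means = tapply(d$value, d$condition, mean),
                          zero_variance = TRUE),
                     class = "group_comparison"))
  }
  fit <- stats::aov(value ~ condition, data = d)
  tab <- summary(fit)[[1]]
  pw <- stats::pairwise.t.test(d$value, d$condition,
                               p.adjust.method = "holm", pool.sd = TRUE)
  structure(list(feature = feature,
                 F = tab[["F value"]][1],
                 df = c(tab[["Df"]][1], tab[["Df"]][2]),
                 p_value = tab[["Pr(>F)"]][1],
                 pairwise = pw$p.value,
                 group_means = tapply(d$value, d$condition, mean),
                 zero_variance = FALSE),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("One-way ANOVA for '%s': F(%d, %d) = %.3g, p = %.3g %s\n",
              x$feature, x$df[1], x$df[2], x$F, x$p_value,
              significance_marker(x$p_value)))
  if (!is.null(x$pairwise)) {
    cat("Holm-adjusted pairwise p values:\n")
    print(round(x$pairwise, 4))
  }
  invisible(x)
}

#' Significance marker at the conventional tiers
#'
#' Renders a p value as `***`/`**`/`*` (p < 0.001 / 0.01 / 0.05) or `ns`.
#' With `style = "dollar"` the `$` glyph family is used instead, the
#' convention for comparisons against the fresh-tissue (0 h) reference group.
#'
#' @param p P value(s).
#' @param style `"star"` or `"dollar"`.
#' @return Character vector of markers.
#' @export
significance_marker <- function(p, style = c("star", "dollar")) {
  style <- match.arg(style)
  sym <- if (style == "star") "*" else "$"
  vapply(p, function(pp) {
    if (is.na(pp)) return("")
    if (pp < 0.001) strrep(sym, 3)
    else if (pp < 0.01) strrep(sym, 2)
    else if (pp < 0.05) sym
    else "ns"
  }, character(1))
}

#' Condition-level summary: mean and standard error
#'
#' @param table Data frame with columns `condition`, `feature`, `value`.
#' @return Data frame with one row per (feature, condition): `n`, `mean`,
#'   `se` (sd / sqrt(n)).
#' @export
condition_summary <- function(table) {
  stopifnot(all(c("condition", "feature", "value") %in% names(table)))
  sp <- split(table, list(table$feature, table$condition), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d)
    data.frame(feature = d$feature[1], condition = d$condition[1],
               n = nrow(d), mean = mean(d$value), se = se(d$value))))
  rownames(out) <- NULL
  out[order(out$feature, out$condition), ]
}
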