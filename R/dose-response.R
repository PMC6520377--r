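## Four-parameter logistic response curve and its least-squares fit.

#' Four-parameter logistic function
#'
#' `bottom + (top - bottom) / (1 + (ec50 / c)^hill)`.  At `c = ec50` the
#' response is the midpoint `(bottom + top) / 2`; as `c -> Inf` it approaches
#' `top`.
#'
#' @param conc Concentration(s), M.
#' @param bottom,top Lower / upper asymptotes.
#' @param ec50 Half-maximal concentration (M).
#' @param hill Hill coefficient.
#' @return Response value(s).
#' @export
four_pl <- function(conc, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (ec50 / conc)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL fit on the log10-concentration scale (the EC50 is
#' estimated as log10(EC50), keeping it positive by construction).  Starting
#' values come from the response range and linear interpolation of the
#' mid-response concentration.
#'
#' @param concentrations_M Positive concentrations (M), at least 5 distinct
#'   levels.
#' @param responses Responses, same length, finite.
#' @return Object of class `dose_response_fit`: `ec50_M`, `hill`, `bottom`,
#'   `top`, `rss`, `n`, and the underlying Levenberg-Marquardt fit object
#'   (`minpack.lm::nls.lm`).
#' @examples
#' d <- gen_dose_response(ec50_M = 1e-8, seed = 1)$table
#' fit_dose_response(d$concentration_M, d$response)
#' @export
fit_dose_response <- function(concentrations_M, responses) {
  if (length(concentrations_M) != length(responses))
    stopf("concentrations and responses differ in length")
  if (any(!is.finite(responses))) stopf("responses must be finite")
  if (any(concentrations_M <= 0)) stopf("concentrations must be positive")
  if (length(unique(concentrations_M)) < 5)
    stopf("at least 5 concentration levels are required")
  rng <- range(responses)
  if (diff(rng) == 0)
    stopf("responses are constant: no dose-response relationship to fit")
  lx <- log10(concentrations_M)
  # initial EC50: concentration whose (monotone-smoothed) response first
  # crosses the mid-range
  mid <- mean(rng)
  ord <- order(lx)
  smoothed <- stats::approx(lx[ord], cummax(responses[ord]), xout = lx[ord])$y
  above <- which(smoothed >= mid)
  lec0 <- if (length(above)) lx[ord][above[1]] else stats::median(lx)
  start <- c(bottom = rng[1], top = rng[2], lec50 = lec0, hill = 1)
  resid_fn <- function(p)
    responses - (p["bottom"] + (p["top"] - p["bottom"]) /
                   (1 + 10^((p["lec50"] - lx) * p["hill"])))
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- fit$par
  ok_codes <- 1:4  # nls.lm convergence diagnostics: 1-4 indicate success
  if (!(fit$info %in% ok_codes) || any(!is.finite(unlist(cf))))
    stopf("4PL fit failed to converge: %s", fit$message)
  structure(list(ec50_M = unname(10^cf["lec50"]), hill = unname(cf["hill"]),
                 bottom = unname(cf["bottom"]), top = unname(cf["top"]),
                 rss = fit$deviance, n = length(responses),
                 fit = fit),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, digits = 4, ...) {
  cat("Four-parameter logistic dose-response fit\n")
  cat(sprintf("  EC50 = %.4g M (log10 = %.3f), Hill = %.3g\n",
              x$ec50_M, log10(x$ec50_M), x$hill))
  cat(sprintf("  bottom = %.4g, top = %.4g, RSS = %.3g (n = %d)\n",
              x$bottom, x$top, x$rss, x$n))
  invisible(x)
}

#' @export
coef.dose_response_fit <- function(object, ...) {
  c(bottom = object$bottom, top = object$top,
    ec50_M = object$ec50_M, hill = object$hill)
}

#' @rdname fit_dose_response
#' @param object A `dose_response_fit`.
#' @param conc Concentrations (M) at which to evaluate the fitted curve.
#' @param ... Unused.
#' @export
predict.dose_response_fit <- function(object, conc, ...) {
  four_pl(conc, object$bottom, object$top, object$ec50_M, object$hill)
}

#' @export
plot.dose_response_fit <- function(x, data = NULL, ...) {
  cc <- 10^seq(log10(x$ec50_M) - 3, log10(x$ec50_M) + 3, length.out = 200)
  graphics::plot(log10(cc), predict(x, cc), type = "l",
                 xlab = "log10 concentration (M)", ylab = "response", ...)
  if (!is.null(data))
    graphics::points(log10(data$concentration_M), data$response)
  invisible(x)
}
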