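#' Metric configuration
#'
#' Tunables shared by the metric bundle. `auc_baseline` is the inhibition
#' floor subtracted before the trapezoidal AUC (default 10%). The Xepto50
#' score always uses a 50% inhibition baseline; its only tunable is the
#' log10-concentration window width `xepto_window` (default 2, i.e. a
#' hundred-fold concentration span starting at the interpolated IC50).
#' `dss_threshold` is the minimum-activity level of the drug sensitivity
#' scores (default 10%). `tested_range` is `c(log10 min, log10 max)` of the
#' tested concentrations; when `NULL` it is taken from the series being
#' scored.
#'
#' @param auc_baseline percent inhibition in `[0, 100)`.
#' @param xepto_window log10-concentration width, > 0.
#' @param dss_threshold percent inhibition in `[0, 100)`.
#' @param tested_range optional `c(xmin, xmax)` in log10 molar.
#' @return an object of class `metric_config`.
#' @export
metric_config <- function(auc_baseline = 10, xepto_window = 2,
                          dss_threshold = 10, tested_range = NULL) {
  stopifnot(auc_baseline >= 0, auc_baseline < 100,
            xepto_window > 0,
            dss_threshold >= 0, dss_threshold < 100)
  if (!is.null(tested_range)) {
    stopifnot(length(tested_range) == 2, tested_range[2] > tested_range[1])
  }
  structure(list(auc_baseline = auc_baseline, xepto_baseline = 50,
                 xepto_window = xepto_window, dss_threshold = dss_threshold,
                 tested_range = tested_range),
            class = "metric_config")
}

# numerically stable log(1 + exp(t))
softplus <- function(t) pmax(t, 0) + log1p(exp(-abs(t)))

# antiderivative of the 4PL over x = log10 concentration:
#   F(x) = a x + (b - a) / (h ln 10) * ln(1 + 10^{h (x - m)})
pl4_antiderivative <- function(p, x) {
  p[1] * x + (p[2] - p[1]) / (p[3] * log(10)) * softplus(p[3] * (x - p[4]) * log(10))
}

# exact integral of the fitted curve between x1 and x2 (log10 molar)
pl4_integral <- function(p, x1, x2) {
  pl4_antiderivative(p, x2) - pl4_antiderivative(p, x1)
}

# log10 concentration where the fitted curve crosses `level`; NA when the
# level is outside the open interval (response_min, response_max)
pl4_crossing <- function(p, level) {
  if (!(p[1] < level && level < p[2])) return(NA_real_)
  p[4] - (1 / p[3]) * log10((p[2] - level) / (level - p[1]))
}

#' Interpolated (absolute) IC50
#'
#' The unique concentration at which the fitted curve crosses 50% inhibition,
#' solved in closed form. Distinct from the traditional (relative) IC50 - the
#' fitted midpoint - whenever the curve is not symmetric about 50%. Undefined
#' (`NA`) when 50% lies outside the open span of the fitted asymptotes, or
#' when the fit did not converge.
#'
#' @param fit a `logistic_fit`.
#' @return molar concentration, or `NA`.
#' @export
interpolated_ic50 <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!fit$converged) return(NA_real_)
  x <- pl4_crossing(as_param_vector(fit), 50)
  if (is.na(x)) NA_real_ else 10^x
}

#' Trapezoidal AUC over log10 concentration
#'
#' Area of the mean inhibition above `auc_baseline` (clamped at zero below
#' it), integrated by the trapezoid rule on the observed means over log10
#' concentration across the tested range - the spreadsheet convention, on the
#' raw data rather than the fitted curve. A fitted-curve variant is available
#' via `on_fit` for comparison.
#'
#' @param summary a [summarize_series()] result.
#' @param config a [metric_config()].
#' @param on_fit optional converged `logistic_fit`; when supplied the area is
#'   computed from the fitted curve by exact integration instead.
#' @return area in percent x log10(M) units.
#' @export
auc_trapezoid <- function(summary, config = metric_config(), on_fit = NULL) {
  stopifnot(inherits(summary, "series_summary"))
  x <- log10(summary$concentrations)
  if (length(x) < 2) stop("AUC needs >= 2 concentrations", call. = FALSE)
  b <- config$auc_baseline
  if (!is.null(on_fit)) {
    stopifnot(inherits(on_fit, "logistic_fit"), on_fit$converged)
    p <- as_param_vector(on_fit)
    return(pl4_area_above(p, b, min(x), max(x)))
  }
  z <- pmax(summary$mean_response - b, 0)
  sum(diff(x) * (utils::head(z, -1) + utils::tail(z, -1)) / 2)
}

# exact area of the fitted curve above `level`, clamped at 0, over [x1, x2];
# uses the monotone crossing so the clamp is exact, not nodal
pl4_area_above <- function(p, level, x1, x2) {
  if (p[2] <= level) {
    # curve may still start above level if rmin > level (flat-ish); handle
    # by noting monotone curve stays within [rmin, rmax]
    if (p[1] >= level) return(pl4_integral(p, x1, x2) - level * (x2 - x1))
    return(0)
  }
  xc <- pl4_crossing(p, level)
  lo <- if (is.na(xc)) x1 else max(x1, min(xc, x2))
  if (lo >= x2) return(0)
  pl4_integral(p, lo, x2) - level * (x2 - lo)
}

#' Drug sensitivity scores DSS1-DSS3
#'
#' Normalized areas of the fitted curve above a minimum-activity threshold
#' `t` over the tested log10-concentration range, computed from the
#' closed-form logistic integral. With `x1` the first crossing above `t`
#' (or the range start if already above; the score is 0 if the curve never
#' exceeds `t`) and `A` the area between curve and threshold from `x1` to the
#' range end:
#' \itemize{
#'   \item DSS1 = `100 A / ((100 - t)(xmax - xmin))` - area relative to a
#'     full-inhibition box over the whole range;
#'   \item DSS2 = `DSS1 / log10(response_max)` - additionally normalized by
#'     the fitted maximal response, down-weighting low-efficacy curves;
#'   \item DSS3 = `DSS2 (xmax - x1) / (xmax - xmin)` - further scaled by the
#'     fraction of the range over which the drug is active.
#' }
#'
#' @param fit a converged `logistic_fit`.
#' @param config a [metric_config()]; must carry `tested_range`.
#' @param variant 1, 2 or 3.
#' @return the score, or `NA` for a non-convergent fit.
#' @export
dss <- function(fit, config, variant = 1) {
  stopifnot(inherits(fit, "logistic_fit"), variant %in% 1:3)
  if (!fit$converged) return(NA_real_)
  rng <- config$tested_range
  if (is.null(rng)) stop("metric_config needs tested_range for DSS", call. = FALSE)
  p <- as_param_vector(fit)
  t <- config$dss_threshold
  xmin <- rng[1]; xmax <- rng[2]

  if (p[2] <= t) return(0)
  xc <- pl4_crossing(p, t)
  x1 <- if (is.na(xc)) xmin else max(xmin, min(xc, xmax))
  if (x1 >= xmax) return(0)
  A <- pl4_integral(p, x1, xmax) - t * (xmax - x1)
  dss1 <- 100 * A / ((100 - t) * (xmax - xmin))
  if (variant == 1) return(dss1)
  if (p[2] <= 1) return(0)  # log10 normalization undefined at/below 1%
  dss2 <- dss1 / log10(p[2])
  if (variant == 2) return(dss2)
  dss2 * (xmax - x1) / (xmax - xmin)
}

#' The Xepto50 score
#'
#' A position-invariant, shape-sensitive efficacy score: the area between the
#' fitted curve and the 50% inhibition baseline over a log10-concentration
#' window of width `xepto_window` starting at the interpolated IC50,
#' normalized by the total window area `(100 - 50) * window`. Because the
#' window is anchored at the curve's own 50% crossing, any lateral shift of
#' the curve moves the window with it and leaves the score unchanged; the
#' score responds only to shape (hill slope and maximal response). It is 0
#' when the curve never reaches 50% inhibition and lives in `[0, 1]`.
#'
#' @param fit a converged `logistic_fit`.
#' @param config a [metric_config()].
#' @return score in `[0, 1]`, or `NA` for a non-convergent fit.
#' @examples
#' f <- structure(list(response_min = 0, response_max = 100, hillslope = 1,
#'                     log10_ic50 = -7, converged = TRUE), class = "logistic_fit")
#' xepto50_score(f, metric_config())  # 0.70329...
#' @export
xepto50_score <- function(fit, config = metric_config()) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!fit$converged) return(NA_real_)
  p <- as_param_vector(fit)
  C <- config$xepto_window
  x0 <- pl4_crossing(p, 50)
  if (is.na(x0)) return(0)
  # monotone curve with f(x0) = 50 keeps the integrand non-negative on the
  # window; the area-above form clamps defensively all the same
  num <- pl4_area_above(p, 50, x0, x0 + C)
  min(max(num / (50 * C), 0), 1)
}

#' Compute the full metric bundle for one fitted series
#'
#' Traditional and interpolated IC50, trapezoidal AUC, DSS1-3 and the Xepto50
#' score. All fields except the Xepto50 score are `NA` when the fit did not
#' converge; the Xepto50 score is additionally 0 (not `NA`) for a converged
#' curve that never reaches 50% inhibition.
#'
#' @param fit a `logistic_fit`.
#' @param summary the [summarize_series()] result the fit came from.
#' @param config a [metric_config()]; a `NULL` `tested_range` is filled from
#'   the summary.
#' @return an object of class `metric_bundle` (also a one-row list usable with
#'   `as.data.frame`).
#' @export
compute_metrics <- function(fit, summary, config = metric_config()) {
  stopifnot(inherits(fit, "logistic_fit"), inherits(summary, "series_summary"))
  if (is.null(config$tested_range)) {
    config$tested_range <- range(log10(summary$concentrations))
  }
  if (!fit$converged) {
    out <- list(ic50_M = NA_real_, neg_log10_ic50 = NA_real_,
                ic50_interp_M = NA_real_, auc = NA_real_,
                dss1 = NA_real_, dss2 = NA_real_, dss3 = NA_real_,
                xepto50 = NA_real_)
    return(structure(out, class = "metric_bundle"))
  }
  ic50 <- 10^fit$log10_ic50
  structure(
    list(ic50_M = ic50,
         neg_log10_ic50 = -fit$log10_ic50,
         ic50_interp_M = interpolated_ic50(fit),
         auc = auc_trapezoid(summary, config),
         dss1 = dss(fit, config, 1),
         dss2 = dss(fit, config, 2),
         dss3 = dss(fit, config, 3),
         xepto50 = xepto50_score(fit, config)),
    class = "metric_bundle")
}

#' @export
print.metric_bundle <- function(x, ...) {
  cat("<metric bundle>\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
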