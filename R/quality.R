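#' Fit-quality diagnostics
#'
#' The residual-based quality suite for one converged fit: R2 and adjusted R2,
#' the standard error of the estimate Sy.x, RMSE, the Shapiro-Wilk normality
#' p-value of the residuals, explained variance, maximum absolute residual,
#' RMAE and MAPE. Conventions: `sy_x = sqrt(SSE / (n - p))` with `p = 4`
#' fitted parameters; RMAE is the square root of the mean absolute residual
#' (the plain MAE is also reported, as `mae`, to avoid ambiguity); MAPE skips
#' observations equal to zero rather than erroring, since near-zero inhibition
#' at low doses is routine. The Shapiro-Wilk p-value needs at least 5 points
#' and is `NA` below that; R2-type scores are `NA` with a warning when the
#' observations have zero variance.
#'
#' @param fit a converged `logistic_fit` (its residuals are used).
#' @param observed the mean responses the fit was computed on; defaults to
#'   `fit$fitted + fit$residuals`.
#' @return an object of class `quality_report`.
#' @export
quality_report <- function(fit, observed = NULL) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!fit$converged) stop("quality_report requires a converged fit", call. = FALSE)
  r <- fit$residuals
  n <- length(r)
  p <- fit$n_params
  if (is.null(observed)) observed <- fit$fitted + r
  stopifnot(length(observed) == n)

  sse <- sum(r^2)
  sst <- sum((observed - mean(observed))^2)
  zero_var <- sst < .Machine$double.eps * n
  if (zero_var) warning("zero-variance observations: R2 undefined", call. = FALSE)

  r2 <- if (zero_var) NA_real_ else 1 - sse / sst
  adj_r2 <- if (zero_var || n <= p + 1) NA_real_ else 1 - (1 - r2) * (n - 1) / (n - p - 1)
  shapiro_p <- if (n >= 5 && stats::sd(r) > 0) stats::shapiro.test(r)$p.value else NA_real_
  expl_var <- if (zero_var) NA_real_ else 1 - stats::var(r) / stats::var(observed)
  nz <- observed != 0
  mape <- if (any(nz)) 100 * mean(abs(r[nz]) / abs(observed[nz])) else NA_real_

  structure(
    list(r2 = r2,
         adjusted_r2 = adj_r2,
         sy_x = if (n > p) sqrt(sse / (n - p)) else NA_real_,
         rmse = sqrt(sse / n),
         shapiro_p = shapiro_p,
         explained_variance = expl_var,
         max_residual = max(abs(r)),
         rmae = sqrt(mean(abs(r))),
         mae = mean(abs(r)),
         mape = mape),
    class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat("<quality report>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]], digits = 5)))
  invisible(x)
}
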