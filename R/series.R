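#' A single dose-response series
#'
#' One (sample, drug) experiment: a strictly positive, ascending vector of
#' molar concentrations and a matrix of replicate responses already converted
#' to percent inhibition. Concentrations are stored in molar throughout and
#' only transformed to log10(M) inside fitting and metrics, so unit mix-ups
#' cannot propagate silently.
#'
#' @param sample_id,drug_id identifiers for the experiment.
#' @param concentrations numeric vector of molar concentrations, all > 0.
#' @param responses numeric matrix, one row per concentration, one column per
#'   replicate, in percent inhibition. `NA` cells are allowed (blank wells).
#' @return An object of class `dose_response_series`.
#' @export
dose_response_series <- function(sample_id, drug_id, concentrations, responses) {
  responses <- as.matrix(responses)
  if (!is.numeric(concentrations) || anyNA(concentrations)) {
    stop("concentrations must be numeric and non-missing", call. = FALSE)
  }
  if (any(concentrations <= 0)) {
    stop("concentrations must be strictly positive (molar)", call. = FALSE)
  }
  if (anyDuplicated(concentrations)) {
    stop("duplicate concentrations within one series", call. = FALSE)
  }
  if (nrow(responses) != length(concentrations)) {
    stop("response matrix must have one row per concentration", call. = FALSE)
  }
  rownames(responses) <- NULL
  ord <- order(concentrations)
  structure(
    list(sample_id = as.character(sample_id),
         drug_id = as.character(drug_id),
         concentrations = concentrations[ord],
         responses = responses[ord, , drop = FALSE],
         n_replicates = ncol(responses)),
    class = "dose_response_series")
}

#' @export
print.dose_response_series <- function(x, ...) {
  cat(sprintf("<dose-response series: %s / %s, %d concentrations x %d replicates>\n",
              x$sample_id, x$drug_id, length(x$concentrations), x$n_replicates))
  invisible(x)
}

# One-sided Grubbs test for the maximum value. Critical value from the t
# quantile at level alpha/n with n-2 df; returns the index of the flagged
# observation or NA. Zero-variance input never flags.
grubbs_max_index <- function(x, alpha) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) return(NA_integer_)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(NA_integer_)
  g <- (max(x) - mean(x)) / s
  tq <- stats::qt(1 - alpha / n, df = n - 2)
  g_crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  if (g > g_crit) which.max(x) else NA_integer_
}

#' Summarize replicates (means, SEM, optional outlier removal)
#'
#' Collapses replicate wells to one mean response per concentration, the scale
#' on which curves are fitted. The SEM is reported only when a concentration
#' retains at least three replicates (`NA`, never zero, below that). Outlier
#' removal, when enabled, applies a one-sided Grubbs test for the largest
#' replicate at each concentration, iteratively, removing at most one
#' replicate per concentration per pass until no pass flags anything; it is a
#' no-op (with a warning) when the series has fewer than three replicates.
#' A concentration whose replicates are all missing or all removed is dropped
#' with a warning.
#'
#' @param series a [dose_response_series()].
#' @param outliers logical; run Grubbs screening (default `FALSE`).
#' @param alpha significance level of the Grubbs test (default 0.05).
#' @return An object of class `series_summary` with elements `concentrations`,
#'   `mean_response`, `sem`, `n_used`, `outlier_mask` (same shape as the
#'   replicate matrix; `TRUE` marks a removed cell), and the parent ids.
#' @export
summarize_series <- function(series, outliers = FALSE, alpha = 0.05) {
  stopifnot(inherits(series, "dose_response_series"))
  resp <- series$responses
  mask <- matrix(FALSE, nrow(resp), ncol(resp))

  if (outliers && series$n_replicates < 3) {
    warning("outlier removal requires >= 3 replicates; skipped", call. = FALSE)
    outliers <- FALSE
  }
  if (outliers) {
    repeat {
      flagged_any <- FALSE
      for (i in seq_len(nrow(resp))) {
        vals <- resp[i, ]
        vals[mask[i, ]] <- NA
        if (sum(!is.na(vals)) < 3) next
        j <- grubbs_max_index(vals, alpha)
        if (!is.na(j)) {
          # index j refers to the surviving values; map back to the column
          live <- which(!is.na(vals))
          mask[i, live[j]] <- TRUE
          flagged_any <- TRUE
        }
      }
      if (!flagged_any) break
    }
  }

  surv <- resp
  surv[mask] <- NA
  n_used <- rowSums(!is.na(surv))
  mean_response <- rowMeans(surv, na.rm = TRUE)
  sem <- apply(surv, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) >= 3) stats::sd(v) / sqrt(length(v)) else NA_real_
  })

  keep <- n_used > 0
  if (any(!keep)) {
    warning(sprintf("dropping %d concentration(s) with no surviving replicates",
                    sum(!keep)), call. = FALSE)
  }
  structure(
    list(sample_id = series$sample_id,
         drug_id = series$drug_id,
         concentrations = series$concentrations[keep],
         mean_response = unname(mean_response[keep]),
         sem = unname(sem[keep]),
         n_used = unname(n_used[keep]),
         n_replicates = series$n_replicates,
         outlier_mask = mask),
    class = "series_summary")
}

#' @export
print.series_summary <- function(x, ...) {
  cat(sprintf("<series summary: %s / %s, %d concentrations, %d outlier cell(s) removed>\n",
              x$sample_id, x$drug_id, length(x$concentrations), sum(x$outlier_mask)))
  invisible(x)
}
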