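#' Analyze one series end to end
#'
#' Summarize replicates (with optional outlier removal), fit the 4PL in two
#' stages, and compute the metric bundle and quality report. Never raises on
#' a pathological series: a non-convergent fit yields `NA` metrics and a
#' status reason.
#'
#' @param series a [dose_response_series()].
#' @param config a [metric_config()].
#' @param outliers,alpha passed to [summarize_series()].
#' @return list with `summary`, `fit`, `metrics`, `quality` (NULL when not
#'   converged) and `status` (`"ok"` or `"no_fit"`).
#' @export
analyze_series <- function(series, config = metric_config(),
                           outliers = FALSE, alpha = 0.05) {
  summary <- summarize_series(series, outliers = outliers, alpha = alpha)
  fit <- tryCatch(fit_logistic(summary), error = function(e) {
    new_logistic_fit(rep(NA_real_, 4), FALSE, reason = conditionMessage(e))
  })
  metrics <- compute_metrics(fit, summary, config)
  quality <- if (fit$converged) quality_report(fit) else NULL
  list(summary = summary, fit = fit, metrics = metrics, quality = quality,
       status = if (fit$converged) "ok" else "no_fit")
}

quality_na <- function() {
  stats::setNames(as.list(rep(NA_real_, 10)),
                  c("r2", "adjusted_r2", "sy_x", "rmse", "shapiro_p",
                    "explained_variance", "max_residual", "rmae", "mae", "mape"))
}

#' Assemble the batch results table
#'
#' One row per analyzed series: identifiers, fit status and parameters, the
#' full metric bundle and the quality suite. Non-convergent fits keep their
#' row with status `"no_fit"`, a reason, and empty (`NA`) metric cells.
#'
#' @param analyses list of [analyze_series()] results.
#' @return a `data.frame`.
#' @export
results_table <- function(analyses) {
  rows <- lapply(analyses, function(a) {
    q <- if (is.null(a$quality)) quality_na() else unclass(a$quality)
    data.frame(
      sample = a$summary$sample_id, drug = a$summary$drug_id,
      status = a$status,
      reason = if (is.na(a$fit$reason)) "" else a$fit$reason,
      response_min = if (a$status == "ok") a$fit$response_min else NA_real_,
      response_max = if (a$status == "ok") a$fit$response_max else NA_real_,
      hillslope = if (a$status == "ok") a$fit$hillslope else NA_real_,
      log10_ic50 = if (a$status == "ok") a$fit$log10_ic50 else NA_real_,
      as.data.frame(unclass(a$metrics)), as.data.frame(q),
      stringsAsFactors = FALSE)
  })
  if (length(rows) == 0) {
    cols <- c("sample", "drug", "status", "reason", "response_min",
              "response_max", "hillslope", "log10_ic50",
              "ic50_M", "neg_log10_ic50", "ic50_interp_M", "auc",
              "dss1", "dss2", "dss3", "xepto50", names(quality_na()))
    return(stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))), cols))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the results table to disk
#'
#' CSV output (UTF-8). An `.xlsx` extension is rejected with an informative
#' error: no spreadsheet writer is bundled, and CSV opens in any spreadsheet
#' application.
#'
#' @param table a [results_table()] data.frame.
#' @param path output path ending in `.csv`.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  if (tolower(tools::file_ext(path)) %in% c("xlsx", "xls")) {
    stop("xlsx output is not supported; write a .csv instead", call. = FALSE)
  }
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Plot one fitted series
#'
#' Mean percent inhibition (with SEM bars when available) against log10
#' concentration, overlaid with the fitted 4PL curve when the fit converged.
#'
#' @param analysis an [analyze_series()] result.
#' @return a ggplot object.
#' @export
plot_series <- function(analysis) {
  s <- analysis$summary
  df <- data.frame(x = log10(s$concentrations), y = s$mean_response, sem = s$sem)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "log10 concentration (M)", y = "inhibition (%)",
                  title = sprintf("%s / %s", s$sample_id, s$drug_id),
                  subtitle = if (analysis$status == "ok") {
                    sprintf("IC50 = %.3g M, Xepto50 = %.3f",
                            analysis$metrics$ic50_M, analysis$metrics$xepto50)
                  } else {
                    paste("no fit:", analysis$fit$reason)
                  }) +
    ggplot2::theme_bw()
  if (any(!is.na(df$sem))) {
    gg <- gg + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$y - .data$sem, ymax = .data$y + .data$sem),
      width = 0.08, na.rm = TRUE)
  }
  if (analysis$status == "ok") {
    p <- as_param_vector(analysis$fit)
    xs <- seq(min(df$x), max(df$x), length.out = 200)
    curve <- data.frame(x = xs, y = eval_4pl_logx(p, xs))
    gg <- gg + ggplot2::geom_line(data = curve, colour = "steelblue")
  }
  gg
}

#' Run configuration for a batch analysis
#'
#' All defaults resolve without a config file; values read from a plain
#' `key = value` text file override the defaults, and explicit arguments
#' (e.g. CLI flags) override the file.
#'
#' @param input input spreadsheet path.
#' @param output_dir directory for the results table, plots and run log.
#' @param convention a [response_convention()].
#' @param schema a [batch_schema()].
#' @param metric a [metric_config()].
#' @param outliers,alpha Grubbs screening toggle and level.
#' @param plots write per-series PNG plots.
#' @param seed seed for any stochastic step (none in the analysis path; kept
#'   for reproducibility of extensions).
#' @return an object of class `run_config`.
#' @export
run_config <- function(input, output_dir = ".",
                       convention = response_convention("inhibition", "percent"),
                       schema = batch_schema(), metric = metric_config(),
                       outliers = FALSE, alpha = 0.05, plots = FALSE,
                       seed = 1L) {
  structure(list(input = input, output_dir = output_dir,
                 convention = convention, schema = schema, metric = metric,
                 outliers = outliers, alpha = alpha, plots = plots,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run a full batch analysis
#'
#' Ingest, per-series analysis, results table, optional plots and a run log.
#' One pathological series never aborts the batch or perturbs another
#' series' results. The exit status is 0 when at least one series converged,
#' 1 otherwise.
#'
#' @param config a [run_config()].
#' @return list with `table` (the results data.frame), `analyses`, `paths`
#'   of written artifacts, and `status` (0 or 1), invisibly.
#' @export
run_batch <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, "run.log")
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  set.seed(config$seed)
  series <- read_batch(config$input, config$convention, config$schema)
  note("read %d series from %s", length(series), config$input)

  analyses <- lapply(series, function(s) {
    a <- withCallingHandlers(
      analyze_series(s, config$metric, config$outliers, config$alpha),
      warning = function(w) {
        note("WARN [%s/%s] %s", s$sample_id, s$drug_id, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (a$status != "ok") {
      note("WARN [%s/%s] no fit: %s", s$sample_id, s$drug_id, a$fit$reason)
    }
    a
  })

  table <- results_table(analyses)
  results_path <- file.path(config$output_dir, "results.csv")
  write_results(table, results_path)
  paths <- results_path

  if (config$plots) {
    for (a in analyses) {
      f <- file.path(config$output_dir,
                     sprintf("%s_%s.png", a$summary$sample_id, a$summary$drug_id))
      ggplot2::ggsave(f, plot_series(a), width = 5, height = 4, dpi = 120)
      paths <- c(paths, f)
    }
  }
  n_ok <- sum(table$status == "ok")
  note("converged %d / %d series", n_ok, nrow(table))
  writeLines(log_lines, log_path)
  invisible(list(table = table, analyses = analyses,
                 paths = c(paths, log_path),
                 status = if (n_ok >= 1) 0L else 1L))
}

#' Read a plain key-value config file
#'
#' Lines of the form `key = value`; `#` starts a comment. Recognized keys
#' mirror the [run_config()] arguments (`input`, `output_dir`, `convention`,
#' `scale`, `auc_baseline`, `xepto_window`, `dss_threshold`, `outliers`,
#' `alpha`, `plots`, `seed`).
#'
#' @param path config file path.
#' @return named character vector.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "),
                     call. = FALSE)
  stats::setNames(vapply(kv, `[[`, "", 2), vapply(kv, `[[`, "", 1))
}
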