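#' Specification for a synthetic dose-response fixture
#'
#' Defines the ground truth and noise model for one simulated (sample, drug)
#' series. Defaults mirror a standard 72-hour viability screen: ten
#' concentrations log-spaced from 5 pM to 10 uM, three replicates, and
#' homoscedastic Gaussian noise of 2% inhibition. Optional outliers shift a
#' random subset of wells by a fixed amount, emulating sporadic well failures.
#' Responses are generated in percent inhibition and then converted *out* to
#' the requested convention, so reading a fixture back exercises the ingest
#' conversion path.
#'
#' @param true_params `c(response_min, response_max, hillslope, log10_ic50)`;
#'   default `c(0, 100, 1, -7.5)`.
#' @param concentrations molar concentrations; default 10 points log-spaced
#'   over 5e-12 to 1e-5 M.
#' @param n_replicates replicate wells per concentration (default 3).
#' @param noise_sd Gaussian noise SD in percent inhibition (default 2).
#' @param outlier_rate per-cell probability of an injected outlier (default 0).
#' @param outlier_shift percent inhibition added to an outlier cell (default 40).
#' @param convention the [response_convention()] the fixture is written in.
#' @param seed integer seed; generation is fully determined by it.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(true_params = c(0, 100, 1, -7.5),
                           concentrations = 10^seq(log10(5e-12), log10(1e-5),
                                                   length.out = 10),
                           n_replicates = 3, noise_sd = 2,
                           outlier_rate = 0, outlier_shift = 40,
                           convention = response_convention("inhibition", "percent"),
                           seed = 1L) {
  stopifnot(length(true_params) == 4, noise_sd >= 0,
            outlier_rate >= 0, outlier_rate <= 1,
            all(concentrations > 0), !anyDuplicated(concentrations),
            n_replicates >= 1)
  structure(list(true_params = true_params, concentrations = concentrations,
                 n_replicates = n_replicates, noise_sd = noise_sd,
                 outlier_rate = outlier_rate, outlier_shift = outlier_shift,
                 convention = convention, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate one synthetic series with known ground truth
#'
#' Evaluates the true 4PL curve at the spec's concentrations, adds seeded
#' Gaussian noise per replicate well, injects outliers at the stated rate,
#' converts the result into the spec's response convention, and returns both
#' the raw (convention-space) response matrix and a ready-made
#' [dose_response_series()] in percent inhibition.
#'
#' @param spec a [synthetic_spec()].
#' @param sample_id,drug_id identifiers for the emitted series.
#' @return list with `series` (a `dose_response_series`), `responses_raw`
#'   (matrix in the spec's convention), `outlier_cells` (logical matrix of
#'   injected outliers) and `spec` (the ground truth).
#' @export
generate_series <- function(spec, sample_id = "S1", drug_id = "D1") {
  stopifnot(inherits(spec, "synthetic_spec"))
  nc <- length(spec$concentrations)
  nr <- spec$n_replicates
  truth <- evaluate_4pl(spec$true_params, spec$concentrations)

  set.seed(spec$seed)
  noise <- if (spec$noise_sd > 0) {
    matrix(stats::rnorm(nc * nr, 0, spec$noise_sd), nc, nr)
  } else {
    matrix(0, nc, nr)
  }
  outlier_cells <- if (spec$outlier_rate > 0) {
    matrix(stats::runif(nc * nr) < spec$outlier_rate, nc, nr)
  } else {
    matrix(FALSE, nc, nr)
  }
  inhib <- truth + noise + outlier_cells * spec$outlier_shift
  raw <- matrix(from_percent_inhibition(inhib, spec$convention), nc, nr)
  # round-trip through the convention so the stored series matches a file read
  series <- dose_response_series(
    sample_id, drug_id, spec$concentrations,
    matrix(to_percent_inhibition(raw, spec$convention), nc, nr))
  list(series = series, responses_raw = raw,
       outlier_cells = outlier_cells, spec = spec)
}

#' Write synthetic series to a batch spreadsheet fixture
#'
#' Emits a CSV in the default batch schema (`sample`, `drug`,
#' `concentration`, `response1..N`) ingestible by [read_batch()], plus a
#' sidecar `<path>.truth.csv` recording each series' ground-truth parameters.
#'
#' @param generated list of [generate_series()] results (may carry distinct
#'   sample/drug ids).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(generated, path) {
  stopifnot(length(generated) >= 1)
  rows <- lapply(generated, function(g) {
    s <- g$series
    raw <- g$responses_raw
    colnames(raw) <- paste0("response", seq_len(ncol(raw)))
    data.frame(sample = s$sample_id, drug = s$drug_id,
               concentration = s$concentrations, raw,
               check.names = FALSE)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE)
  truth <- do.call(rbind, lapply(generated, function(g) {
    data.frame(sample = g$series$sample_id, drug = g$series$drug_id,
               response_min = g$spec$true_params[1],
               response_max = g$spec$true_params[2],
               hillslope = g$spec$true_params[3],
               log10_ic50 = g$spec$true_params[4],
               noise_sd = g$spec$noise_sd, seed = g$spec$seed)
  }))
  utils::write.csv(truth, paste0(path, ".truth.csv"), row.names = FALSE)
  invisible(path)
}
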