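#' Column mapping for batch spreadsheets
#'
#' The default schema expects columns named `sample`, `drug` and
#' `concentration` (molar), with replicate responses in every column whose
#' header starts with `response` (case-insensitive). When no header matches
#' that prefix, all remaining numeric columns are taken as responses. Every
#' name is overridable.
#'
#' @param sample,drug,concentration column names for the identifiers and the
#'   molar concentration.
#' @param response_prefix header prefix marking response columns.
#' @return an object of class `batch_schema`.
#' @export
batch_schema <- function(sample = "sample", drug = "drug",
                         concentration = "concentration",
                         response_prefix = "response") {
  structure(list(sample = sample, drug = drug, concentration = concentration,
                 response_prefix = response_prefix),
            class = "batch_schema")
}

read_sheet <- function(path, sheet = 1) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    utils::read.csv(path, check.names = FALSE)
  }
}

#' Read a batch spreadsheet into dose-response series
#'
#' Ingests one Excel (first sheet by default) or CSV file holding any number
#' of experiments - one row per (sample, drug, concentration), replicates in
#' columns - and returns one [dose_response_series()] per unique
#' (sample, drug) pair, with all responses converted to percent inhibition
#' and concentrations sorted ascending. The number of response columns is
#' detected from the header prefix, falling back to all unmapped numeric
#' columns. Blank replicate cells are allowed and skipped downstream;
#' duplicate (sample, drug, concentration) rows are an error.
#'
#' @param path `.csv`, `.xlsx` or `.xls` file.
#' @param convention the [response_convention()] the file's responses are in.
#' @param schema a [batch_schema()] mapping column names.
#' @param sheet sheet index or name for Excel input.
#' @return list of `dose_response_series`.
#' @export
read_batch <- function(path, convention = response_convention("inhibition", "percent"),
                       schema = batch_schema(), sheet = 1) {
  stopifnot(inherits(schema, "batch_schema"))
  tab <- read_sheet(path, sheet)

  for (col in c(schema$sample, schema$drug, schema$concentration)) {
    if (!col %in% names(tab)) {
      stop(sprintf("required column '%s' is missing from %s", col, basename(path)),
           call. = FALSE)
    }
  }
  resp_cols <- grep(paste0("^", schema$response_prefix), names(tab),
                    ignore.case = TRUE, value = TRUE)
  if (length(resp_cols) == 0) {
    other <- setdiff(names(tab), c(schema$sample, schema$drug, schema$concentration))
    resp_cols <- other[vapply(tab[other], is.numeric, logical(1))]
  }
  if (length(resp_cols) == 0) {
    stop("no response columns found (prefix '", schema$response_prefix,
         "', and no numeric fallback columns)", call. = FALSE)
  }

  conc <- suppressWarnings(as.numeric(tab[[schema$concentration]]))
  bad <- which(is.na(conc) | conc <= 0)
  if (length(bad) > 0) {
    stop(sprintf("non-positive or non-numeric concentration at data row(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }

  key <- interaction(tab[[schema$sample]], tab[[schema$drug]], drop = TRUE, sep = "\r")
  lapply(split(seq_len(nrow(tab)), key), function(idx) {
    sub <- tab[idx, , drop = FALSE]
    if (anyDuplicated(conc[idx])) {
      stop(sprintf("duplicate concentration rows for (%s, %s)",
                   sub[[schema$sample]][1], sub[[schema$drug]][1]), call. = FALSE)
    }
    resp <- as.matrix(sub[, resp_cols, drop = FALSE])
    storage.mode(resp) <- "double"
    dose_response_series(sub[[schema$sample]][1], sub[[schema$drug]][1],
                         conc[idx], to_percent_inhibition(resp, convention))
  })
}
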