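make_batch_fixture <- function(path, flat = FALSE) {
  gen <- list()
  k <- 0
  for (s in c("S1", "S2")) {
    for (d in c("D1", "D2", "D3")) {
      k <- k + 1
      p <- if (flat) c(0, 0, 1, -7) else c(0, 100 - 5 * k, 0.8 + 0.2 * k, -8 + 0.3 * k)
      gen[[k]] <- generate_series(synthetic_spec(true_params = p,
                                                 noise_sd = if (flat) 0 else 2,
                                                 seed = 100 + k), s, d)
    }
  }
  write_fixture(gen, path)
  path
}

test_that("a batch run analyzes every series and reports success", {
  f <- make_batch_fixture(tempfile(fileext = ".csv"))
  out <- file.path(tempdir(), "run_ok")
  res <- suppressMessages(run_batch(run_config(f, output_dir = out)))
  expect_equal(nrow(res$table), 6)
  expect_true(all(res$table$status == "ok"))
  expect_equal(res$status, 0L)
  expect_true(file.exists(file.path(out, "results.csv")))
  expect_true(file.exists(file.path(out, "run.log")))
  expect_true(all(c("ic50_M", "neg_log10_ic50", "ic50_interp_M", "auc",
                    "dss1", "dss2", "dss3", "xepto50", "r2", "rmse") %in%
                    names(res$table)))
})

test_that("an all-flat batch exits nonzero with every series flagged, none raised", {
  f <- make_batch_fixture(tempfile(fileext = ".csv"), flat = TRUE)
  out <- file.path(tempdir(), "run_flat")
  res <- suppressMessages(run_batch(run_config(f, output_dir = out)))
  expect_equal(nrow(res$table), 6)
  expect_true(all(res$table$status == "no_fit"))
  expect_equal(res$status, 1L)
  expect_true(all(is.na(res$table$ic50_M)))
})

test_that("one pathological series never perturbs the others", {
  gen <- list(
    generate_series(synthetic_spec(true_params = c(0, 95, 1, -7.5),
                                   noise_sd = 2, seed = 1), "S1", "good"),
    generate_series(synthetic_spec(true_params = c(0, 0, 1, -7),
                                   noise_sd = 0, seed = 2), "S1", "flat"))
  f_both <- tempfile(fileext = ".csv"); write_fixture(gen, f_both)
  f_good <- tempfile(fileext = ".csv"); write_fixture(gen[1], f_good)
  out_both <- suppressMessages(run_batch(run_config(f_both, tempdir())))
  out_good <- suppressMessages(run_batch(run_config(f_good, tempdir())))
  both_row <- out_both$table[out_both$table$drug == "good", ]
  good_row <- out_good$table
  rownames(both_row) <- rownames(good_row) <- NULL
  expect_equal(both_row, good_row)
})

test_that("identical input and config give byte-identical result tables", {
  f <- make_batch_fixture(tempfile(fileext = ".csv"))
  out1 <- file.path(tempdir(), "det1"); out2 <- file.path(tempdir(), "det2")
  suppressMessages(run_batch(run_config(f, out1)))
  suppressMessages(run_batch(run_config(f, out2)))
  expect_identical(readLines(file.path(out1, "results.csv")),
                   readLines(file.path(out2, "results.csv")))
})

test_that("result writing covers empty batches and rejects xlsx output", {
  empty <- results_table(list())
  expect_equal(nrow(empty), 0)
  f <- tempfile(fileext = ".csv")
  write_results(empty, f)
  expect_length(readLines(f), 1)  # header only
  expect_error(write_results(empty, tempfile(fileext = ".xlsx")), "xlsx")
})

test_that("plain key-value config files parse with comments and blanks", {
  f <- tempfile(fileext = ".cfg")
  writeLines(c("# batch defaults", "", "auc_baseline = 10",
               "xepto_window = 2.0  # log units", "outliers = true"), f)
  kv <- read_run_config(f)
  expect_equal(kv[["auc_baseline"]], "10")
  expect_equal(kv[["xepto_window"]], "2.0")
  expect_equal(kv[["outliers"]], "true")
  writeLines("auc_baseline 10", f)
  expect_error(read_run_config(f), "malformed")
})

test_that("series plots build for convergent and non-convergent fits", {
  g <- generate_series(synthetic_spec(noise_sd = 2, seed = 3))
  a <- analyze_series(g$series)
  expect_s3_class(plot_series(a), "ggplot")
  flat <- generate_series(synthetic_spec(true_params = c(0, 0, 1, -7),
                                         noise_sd = 0), "S", "flat")
  expect_s3_class(plot_series(analyze_series(flat$series)), "ggplot")
})
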