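default_range <- log10(c(5e-12, 1e-5))

test_that("interpolated IC50 matches the closed form and the bisection oracle", {
  # symmetric curve: the 50% crossing is the midpoint parameter itself
  f_sym <- make_fit(c(0, 100, 1, -7))
  expect_equal(log10(interpolated_ic50(f_sym)), -7, tolerance = 1e-12)

  # asymmetric curve: 10^(-7 - log10(30/50))
  f_asym <- make_fit(c(0, 80, 1, -7))
  expect_equal(interpolated_ic50(f_asym), 10^(-7 - log10(30 / 50)),
               tolerance = 1e-12)
  expect_equal(log10(interpolated_ic50(f_asym)),
               oracle_crossing(c(0, 80, 1, -7), 50), tolerance = 1e-9)
  expect_equal(interpolated_ic50(f_asym), 1.6667e-7, tolerance = 1e-4)

  # curve that never reaches 50% inhibition
  expect_true(is.na(interpolated_ic50(make_fit(c(0, 40, 1, -7)))))
})

test_that("trapezoidal AUC reproduces rectangle cases and the quadrature oracle", {
  conc6 <- 10^seq(-11, -5, 1)  # exactly 6 log units
  flat100 <- dose_response_series("A", "d", conc6, matrix(100, 7, 1))
  expect_equal(auc_trapezoid(summarize_series(flat100), metric_config()), 540)

  flat10 <- dose_response_series("A", "d", conc6, matrix(10, 7, 1))
  expect_equal(auc_trapezoid(summarize_series(flat10), metric_config()), 0)

  r <- fit_noiseless(c(0, 100, 1, -7))
  got <- auc_trapezoid(r$summary, metric_config())
  want <- oracle_trapezoid(log10(r$summary$concentrations),
                           r$summary$mean_response, 10)
  expect_equal(got, want, tolerance = 1e-9)

  one <- dose_response_series("A", "d", 1e-7, matrix(50, 1, 1))
  expect_error(auc_trapezoid(summarize_series(one)), ">= 2 concentrations")
})

test_that("DSS variants match their definitions and the quadrature oracle", {
  cfg <- metric_config(tested_range = default_range)
  # curve entirely below the threshold scores 0 in every variant
  low <- make_fit(c(0, 8, 1, -7))
  for (v in 1:3) expect_equal(dss(low, cfg, v), 0)

  # near-step curve at the range midpoint: half the full-inhibition box
  mid <- mean(default_range)
  step <- make_fit(c(0, 100, 50, mid))
  expect_equal(dss(step, cfg, 1), 50, tolerance = 0.2)
  a_oracle <- oracle_area_above(c(0, 100, 50, mid), 10,
                                default_range[1], default_range[2])
  expect_equal(dss(step, cfg, 1),
               100 * a_oracle / (90 * diff(default_range)), tolerance = 1e-6)

  # randomized fits: every variant against oracle area + stated normalizers
  pars <- random_params(30, seed = 99)
  for (i in seq_len(nrow(pars))) {
    p <- pars[i, ]
    f <- make_fit(p)
    A <- oracle_area_above(p, 10, default_range[1], default_range[2])
    d1 <- 100 * A / ((100 - 10) * diff(default_range))
    expect_equal(dss(f, cfg, 1), d1, tolerance = 1e-6)
    expect_equal(dss(f, cfg, 2), d1 / log10(p[2]), tolerance = 1e-6)
    x1 <- if (p[1] < 10) max(default_range[1], oracle_crossing(p, 10)) else default_range[1]
    expect_equal(dss(f, cfg, 3),
                 d1 / log10(p[2]) * (default_range[2] - x1) / diff(default_range),
                 tolerance = 1e-6)
  }
})

test_that("the Xepto50 score matches its closed-form worked value", {
  f <- make_fit(c(0, 100, 1, -7))
  # closed form: [100 (log10(101) - log10 2) - 100] / 100
  want <- (100 * (log10(101) - log10(2)) - 100) / 100
  expect_equal(xepto50_score(f, metric_config()), want, tolerance = 1e-12)
  expect_equal(xepto50_score(f, metric_config()), 0.70329, tolerance = 1e-4)

  # step-curve limit fills the whole window rectangle; the exact deficit at
  # finite hillslope h is log10(2) * (rmax - rmin) / (h * 50 * C)
  expect_equal(xepto50_score(make_fit(c(0, 100, 100, -7)), metric_config()),
               1 - log10(2) * 100 / (100 * 50 * 2), tolerance = 1e-9)
  expect_equal(xepto50_score(make_fit(c(0, 100, 1000, -7)), metric_config()), 1,
               tolerance = 1e-3)
})

test_that("the Xepto50 score is position-invariant but shape-sensitive", {
  cfg <- metric_config()
  s6 <- xepto50_score(make_fit(c(0, 100, 1, -6)), cfg)
  s8 <- xepto50_score(make_fit(c(0, 100, 1, -8)), cfg)
  expect_equal(s6 - s8, 0, tolerance = 1e-12)

  # strictly increasing in maximal response (above 50) and in hillslope
  rmax_grid <- seq(60, 100, by = 10)
  scores_rmax <- vapply(rmax_grid, function(b)
    xepto50_score(make_fit(c(0, b, 1, -7)), cfg), numeric(1))
  expect_true(all(diff(scores_rmax) > 0))

  hill_grid <- c(0.5, 1, 2, 4, 8)
  scores_hill <- vapply(hill_grid, function(h)
    xepto50_score(make_fit(c(0, 100, h, -7)), cfg), numeric(1))
  expect_true(all(diff(scores_hill) > 0))
})

test_that("lateral shifts move both IC50s by exactly the shift", {
  for (delta in c(-1.5, 0.7, 2)) {
    f0 <- make_fit(c(5, 90, 1.3, -7.5))
    f1 <- make_fit(c(5, 90, 1.3, -7.5 + delta))
    expect_equal(log10(interpolated_ic50(f1)) - log10(interpolated_ic50(f0)),
                 delta, tolerance = 1e-12)
    expect_equal(f1$log10_ic50 - f0$log10_ic50, delta)
  }
})

test_that("Xepto50 stays in [0, 1] and is 0 exactly when 50% is never reached", {
  cfg <- metric_config()
  pars <- random_params(60, seed = 5)
  for (i in seq_len(nrow(pars))) {
    s <- xepto50_score(make_fit(pars[i, ]), cfg)
    expect_gte(s, 0); expect_lte(s, 1)
  }
  expect_equal(xepto50_score(make_fit(c(0, 50, 1, -7)), cfg), 0)
  expect_equal(xepto50_score(make_fit(c(0, 45, 3, -7)), cfg), 0)
  expect_gt(xepto50_score(make_fit(c(0, 50.5, 1, -7)), cfg), 0)
})

test_that("non-convergent fits yield NA metrics except the defined Xepto50 zero", {
  s <- dose_response_series("A", "d", 10^seq(-9, -6, 1), matrix(0, 4, 1))
  sm <- summarize_series(s)
  f <- fit_logistic(sm)
  m <- compute_metrics(f, sm)
  expect_true(all(is.na(unlist(m))))
  expect_true(is.na(xepto50_score(f, metric_config())))
})

test_that("metric bundle fields are mutually consistent", {
  r <- fit_noiseless(c(0, 95, 1.1, -7.2))
  m <- compute_metrics(r$fit, r$summary)
  expect_equal(m$neg_log10_ic50, -log10(m$ic50_M), tolerance = 1e-12)
  expect_lte(m$dss3, m$dss2 + 1e-12)  # range fraction never exceeds 1
})
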