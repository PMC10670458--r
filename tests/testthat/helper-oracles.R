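# Independent oracles used across the suite. These deliberately avoid the
# package's closed-form antiderivative and crossing solver: the curve is
# re-stated directly, crossings come from bisection, and areas from adaptive
# quadrature, so agreement is a genuine dual-route check.

# the 4PL restated from the model definition, on log10 concentration
oracle_4pl <- function(p, x) {
  p[1] + (p[2] - p[1]) / (1 + 10^(p[3] * (p[4] - x)))
}

# bisection solve of oracle_4pl(x) = level
oracle_crossing <- function(p, level, lower = -30, upper = 10) {
  stats::uniroot(function(x) oracle_4pl(p, x) - level,
                 c(lower, upper), tol = 1e-13)$root
}

# adaptive quadrature of max(curve - level, 0) over [x1, x2], split at the
# bisection crossing so the kink never degrades the quadrature
oracle_area_above <- function(p, level, x1, x2) {
  f <- function(x) pmax(oracle_4pl(p, x) - level, 0)
  if (p[1] < level && level < p[2]) {
    xc <- oracle_crossing(p, level)
    if (xc > x1 && xc < x2) {
      return(stats::integrate(f, x1, xc, rel.tol = 1e-12, abs.tol = 1e-12)$value +
             stats::integrate(f, xc, x2, rel.tol = 1e-12, abs.tol = 1e-12)$value)
    }
  }
  stats::integrate(f, x1, x2, rel.tol = 1e-12, abs.tol = 1e-12)$value
}

# adaptive quadrature of the baseline-clamped piecewise-linear interpolant of
# the mean responses, segment by segment (the trapezoid's independent oracle)
oracle_trapezoid <- function(x, y, baseline) {
  g <- stats::approxfun(x, pmax(y - baseline, 0))
  segs <- mapply(function(a, b) {
    stats::integrate(g, a, b, rel.tol = 1e-12, abs.tol = 1e-12)$value
  }, utils::head(x, -1), utils::tail(x, -1))
  sum(segs)
}

# bare converged fit object from a parameter quadruple (for metric tests that
# do not need a fitting step)
make_fit <- function(p) {
  structure(list(response_min = p[1], response_max = p[2], hillslope = p[3],
                 log10_ic50 = p[4], converged = TRUE, reason = NA_character_,
                 residuals = numeric(0), fitted = numeric(0),
                 n_points = 0L, n_params = 4L),
            class = "logistic_fit")
}

# random plausible parameter quadruples; curve crosses 50 within reach
random_params <- function(n, seed) {
  set.seed(seed)
  t(replicate(n, c(runif(1, 0, 15), runif(1, 60, 100),
                   runif(1, 0.4, 4), runif(1, -9.5, -5.5))))
}

# a noiseless series + summary + two-stage fit from a quadruple
fit_noiseless <- function(p, seed = 1) {
  g <- generate_series(synthetic_spec(true_params = p, noise_sd = 0, seed = seed))
  s <- summarize_series(g$series)
  list(summary = s, fit = fit_logistic(s))
}
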