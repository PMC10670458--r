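---
title: "Dose-response curve fitting and the Xepto50 score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-response curve fitting and the Xepto50 score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xepto50r)
```

## The model

Every series in a batch — one (sample, drug) pair with responses at a ladder
of concentrations — is summarized by the four-parameter logistic (4PL) curve
on a log10 molar axis:

$$R(c) = R_{min} + \frac{R_{max} - R_{min}}
  {1 + 10^{\,h\,(\log_{10} IC_{50} - \log_{10} c)}}$$

where $R_{min}$ and $R_{max}$ are the lower and upper asymptotes in percent
inhibition, $h > 0$ is the hill slope (cooperativity), and the midpoint
$IC_{50}$ is the *traditional (relative) IC50*. Because all responses are
converted to percent inhibition on ingest, the curve is always monotone
non-decreasing in concentration; a fit that wants a negative slope is
reported as non-convergent rather than silently flipped, since it indicates
data inconsistent with an inhibition readout.

Responses may arrive as viability or inhibition, as ratios or percentages.
The four conversions to percent inhibition are all affine and exactly
invertible, so the choice of input convention can never change a result
beyond floating-point noise (the suite checks round-trips at 1e-12).

## Replicate handling

Curves are fitted to the **mean** response per concentration; replicate
scatter enters only descriptively, as the SEM, and the SEM is reported only
when at least three replicates survive at a concentration (it is `NA`, never
a misleading zero, below that). Blank cells are skipped; a concentration
losing all its replicates is dropped with a warning.

Optional outlier screening uses a one-sided Grubbs test on the largest
replicate at each concentration (default $\alpha = 0.05$), iterated with at
most one removal per concentration per pass. Grubbs is the standard
deterministic single-outlier test for replicate wells; the one-sided-max
variant targets the common failure mode of a spuriously high inhibition well
(e.g. an empty or contaminated well in a viability assay). The test
requires three replicates and never fires on zero-variance data. Screening
is opt-in: silently deleting data is not a default any analysis should have.

## The two-stage fit

Stage 1 is an unconstrained Levenberg–Marquardt least-squares fit started
from a deterministic heuristic (asymptotes at the extreme means, hill slope
1, midpoint at the tested concentration nearest the half-way response, ties
toward the lower concentration). Stage 2 re-fits from the stage-1 solution
under box constraints:

| parameter        | bounds                       | rationale |
|------------------|------------------------------|-----------|
| $R_{min}$        | $[-10, 60]$ %                | tolerates baseline noise, rejects an upside-down curve |
| $R_{max}$        | $\le 120$ %, $\ge R_{min}$   | tolerates overshoot past full inhibition |
| $h$              | $(0, 20]$                    | positive by construction; 20 is already a near-step curve |
| $\log_{10} IC_{50}$ | tested range $\pm 3$ log units | beyond that the midpoint is not identified by the data |

The refinement can only keep or improve the (clamped) stage-1 sum of squared
errors; if the unconstrained optimum lies far outside the bounds and the
constrained fit is materially worse, the series is flagged rather than
reported. Numeric failure anywhere returns a flagged result, never an error,
so one pathological series cannot abort a batch. Optimizer tolerances
default to `ftol = ptol = 1e-14` with up to 10,000 iterations (the
Levenberg–Marquardt backend caps a stage at 1024), which on noiseless data
from the model class recovers parameters to better than 1e-6.

Whether the upstream tool this design follows fits on means or pooled
replicates, and what bounds it uses, is not documented anywhere we could
find; both are therefore package-level choices, stated here and configurable.

## The metric bundle

* **Traditional IC50** — the fitted midpoint, also reported as
  $-\log_{10} IC_{50}$.
* **Interpolated (absolute) IC50** — the concentration where the fitted
  curve crosses 50% inhibition, in closed form
  $\log_{10} c_{50} = \log_{10} IC_{50} - \frac{1}{h}\log_{10}
  \frac{R_{max} - 50}{50 - R_{min}}$; undefined (reported `NA`) when the
  curve never spans 50%.
* **AUC** — trapezoidal area of the mean inhibition above a baseline
  (default 10%) over log10 concentration, computed on the raw means, which
  is the spreadsheet convention most tools agree on; a fitted-curve variant
  is available behind the `on_fit` argument.
* **DSS1–3** — normalized areas of the *fitted* curve above an activity
  threshold $t$ (default 10%), using the exact logistic antiderivative
  $\int R \, dx = R_{min} x + \frac{R_{max}-R_{min}}{h \ln 10}
  \ln(1 + 10^{h(x - \log_{10} IC_{50})})$. With $A$ the area from the first
  crossing $x_1$ to the range end $x_{max}$:
  $DSS1 = \frac{100\,A}{(100 - t)(x_{max} - x_{min})}$,
  $DSS2 = DSS1 / \log_{10} R_{max}$, and
  $DSS3 = DSS2 \cdot \frac{x_{max} - x_1}{x_{max} - x_{min}}$. These
  normalizations follow the published drug-sensitivity-score conventions;
  the scores themselves are named but not defined by the tool this package
  re-implements, so the constants are documented here as adopted ones and
  every area term is verified against an independent adaptive-quadrature
  oracle in the test suite.
* **Xepto50 score** — the defining metric. Let $x_0$ be the log10 of the
  interpolated IC50 and $C$ a window width in log units (default 2, a
  hundred-fold concentration span). Then

  $$\text{Xepto50} = \frac{\int_{x_0}^{x_0 + C} (R(x) - 50)\,dx}{(100 - 50)\,C}$$

  Because the window is anchored at the curve's own 50% crossing, a lateral
  shift of the curve moves the window with it: the score is *exactly*
  position-invariant and responds only to shape — it increases with hill
  slope and with maximal response. It is 0 when the curve never reaches 50%
  inhibition and is reported on $[0, 1]$ (clamped at 1; a fitted
  $R_{max}$ above 100% could otherwise push it over). The window width is
  not documented by the upstream tool; 2 log units is wide enough to capture
  plateau behavior while staying near the tested range, and is configurable.

For the symmetric reference curve $(0, 100, 1, -7)$ the closed form gives
$\text{Xepto50} = \log_{10} 101 - \log_{10} 2 - 1 = 0.70329$, which the
package reproduces through the full pipeline:

```{r worked}
g <- generate_series(synthetic_spec(true_params = c(0, 100, 1, -7), noise_sd = 0))
a <- analyze_series(g$series)
a$metrics$xepto50
```

A non-convergent fit yields `NA` for every metric; the Xepto50 score is
additionally defined as 0 (not `NA`) for a *converged* curve that never
reaches 50%, since "never 50% inhibited" is a real, minimal-efficacy
observation rather than a missing one.

## Quality suite

Nine residual diagnostics per converged fit: $R^2$, adjusted $R^2$ (with
$p = 4$ parameters), $S_{y.x} = \sqrt{SSE/(n-p)}$, $RMSE = \sqrt{SSE/n}$,
the Shapiro–Wilk normality p-value of the residuals (requires $n \ge 5$),
explained variance, maximum absolute residual, RMAE and MAPE. "RMAE" is
ambiguous in the wild; here it is $\sqrt{\text{mean}|r|}$, and the plain MAE
is emitted under its own column so no reader has to guess. MAPE skips
observations that are exactly zero — near-zero inhibition at the lowest
doses is routine and should not poison the average. The Shapiro–Wilk wiring
is calibrated in the suite: on seeded N(0,1) residuals (1,000 repeats of
$n = 10$) the rejection rate at 0.05 lands in [0.03, 0.07].

## The synthetic generator

`synthetic_spec()` emulates a standard 72-hour viability screen: ten
concentrations log-spaced from 5 pM to 10 µM, three replicates, and
homoscedastic Gaussian noise with SD 2% inhibition added to the true 4PL
signal, with optional outlier cells shifted by +40%. Defaults are the study
conditions the package is tested under; the default truth for documentation
is $(0, 100, 1, -7.5)$, centered in that range. Generation is fully
determined by the seed, and responses are converted *out* of percent
inhibition into the requested convention before writing, so reading a
fixture back exercises the same conversion path real data takes.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: heteroscedastic noise (real viability assays
are noisier mid-curve), plate and edge effects, biphasic or bell-shaped
responses, and correlated replicate errors. The fit bounds and the
non-convergence reporting are the package's defenses when real data departs
from the model class; the simulation results quantify estimator behavior
only under the stated conditions.

Problem sizes used by the checks: single fits are over 10 concentrations;
Monte-Carlo recovery uses 200 seeded series (mean absolute log10-IC50 error
under 2%-noise: about 0.02 log units, an order of magnitude inside the 0.1
acceptance band); oracle comparisons use 100 randomized parameter sets.

## Numerical choices

The logistic antiderivative is evaluated through a stable softplus
($\max(t,0) + \log(1+e^{-|t|})$), so steep slopes and wide windows cannot
overflow. Area-above-threshold terms split the integral at the analytic
crossing, making the clamp at zero exact rather than nodal. Degenerate
inputs are classified, not propagated: flat means (range < 1e-6%) short-
circuit to `converged = FALSE, reason = "flat response"`; zero-variance
observations make $R^2$ `NA` with a warning; identical replicates never
trigger the outlier test. Ties in the initial-guess midpoint go to the
lower concentration, keeping the whole pipeline deterministic — two runs on
the same file produce byte-identical tables.

## Limitations

Only the symmetric 4PL is fitted; asymmetric (5PL) or non-monotone responses
are out of scope and will surface as poor quality scores rather than
alternative fits. The AUC is intentionally data-anchored while DSS and
Xepto50 are fit-anchored, so they react differently to lack of fit. Result
tables are CSV; spreadsheet input may be `.xlsx` or `.csv`.
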