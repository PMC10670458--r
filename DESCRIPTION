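Package: xepto50r
Title: Batch Four-Parameter Logistic Dose-Response Analysis and the
    Xepto50 Drug-Sensitivity Score
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch analysis of high-throughput drug-response (viability or
    inhibition) experiments. Fits the four-parameter logistic model to each
    (sample, drug) series in two stages (unconstrained then bounded nonlinear
    least squares), and computes a bundle of sensitivity metrics: the
    traditional (relative) and interpolated (absolute) IC50, trapezoidal AUC
    over log10 concentration, the drug sensitivity scores DSS1-DSS3, and the
    Xepto50 score, a position-invariant, shape-sensitive normalized area over
    a fixed log-concentration window anchored at the interpolated IC50. Also
    provides fit-quality diagnostics, replicate summarization with Grubbs
    outlier removal, a seeded synthetic-data generator, and a command-line
    batch entry point.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    minpack.lm,
    readxl,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
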