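Package: mcrepeat
Title: Monte Carlo Dropout Inference and Test-Retest Repeatability for
    Ordinal Severity Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the test-retest repeatability and calibration of
    image-based severity classifiers. Provides severity-score mappings for
    binary, multi-class, ordinal (cumulative-link encoded) and regression
    model heads; Monte Carlo dropout inference with seeded per-image draw
    streams and an iteration sweep; Bland-Altman repeatability metrics
    (classification disagreement rate and normalized non-parametric 95%
    limits of agreement); calibration and agreement metrics (Brier score,
    reliability curves, quadratic weighted Cohen's kappa) with grouped
    bootstrap model comparison; a synthetic test-retest image generator with
    an ordinal latent severity, boundary label noise and acquisition jitter;
    and small trainable convolutional models with spatial (channel) dropout
    so the whole pipeline runs on one CPU.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    readr,
    rlang,
    stats,
    tibble,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
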