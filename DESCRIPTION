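Package: subpopq
Title: Quantile-Quantile Detection of Bimodal Subpopulations in
    Single-Cell Fluorescence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to identify and quantify rare high-expressing
    ("transfer-competent") subpopulations of bacteria from per-cell
    fluorescence measurements. Implements subpopulation detection by
    quantile-quantile regression thresholding, paired two-reporter
    colocalization, time-lapse trace onset calling by sliding linear
    regression with moving qq thresholds and carry-over filtering,
    median-of-ratios (pseudoreference) count normalization with a
    bootstrap two-sample t-test, replicate-level statistics (paired
    one-sided t-tests, Bartlett, one-way ANOVA with Tukey compact letter
    display), conjugative transfer-frequency computation, and synthetic
    data generators with known ground truth for validating the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    DESeq2
Config/testthat/edition: 3
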