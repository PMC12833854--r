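Package: tumorkinetics
Title: Exponential Tumor Growth Modeling and Temporal Growth-Rate Matrices
    for Preclinical Studies
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of longitudinal tumor-burden measurements from
    preclinical animal studies. Fits per-animal exponential growth models by
    log-linear regression and reports growth rates with relative standard
    errors, doubling times and goodness-of-fit filtering. Builds temporal
    tumor-growth-rate (TGR) matrices over all time-point pairs, scores
    cohort homogeneity, detects outliers with a six-criteria
    sample-size-adaptive detector, compares groups with Mann-Whitney tests
    and Cohen's d effect sizes, assesses statistical power by repeated
    random subsetting, and standardizes tumor weights across heterogeneous
    euthanasia dates. Includes a synthetic-cohort generator for validation
    and a static HTML report renderer.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Software, Regression, QualityControl, Preprocessing
RoxygenNote: 7.3.3
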