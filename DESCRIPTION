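Package: mammodrl
Title: Model-Based Diagnostic Reference Levels for Mammography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for establishing mammographic diagnostic reference levels
    (DRLs) from exposure metadata. Reads exposure records from DICOM file
    headers or CSV exports, applies examination-level quality exclusions with
    exact accounting, and computes the 75th percentile of per-center median
    average glandular dose (AGD) three ways: for a single typical
    compressed-breast-thickness (CBT) window, per 10-mm CBT bin, and as a
    continuous fitted DRL-versus-CBT curve selected among linear, power and
    exponential model families by trust-region nonlinear least squares.
    Includes approach-comparison statistics (percent differences, exact
    Wilcoxon signed-rank test), classification against guideline limit
    curves, a multi-center synthetic cohort generator with a known
    ground-truth DRL surface, and an end-to-end reporting pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    minpack.lm,
    jsonlite,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
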