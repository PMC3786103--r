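Package: qsarga
Title: Genetic-Algorithm Descriptor Selection and Validation for QSAR Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for quantitative structure-activity
    relationship (QSAR) modelling with multiple linear regression:
    descriptor-table input with IC50-to-pIC50 conversion, constant and
    inter-correlated descriptor filtering, genetic-algorithm and stepwise
    variable selection driven by cross-validated predictive variance,
    leave-one-out / leave-group-out / bootstrap Q2 validation,
    Y-randomization, leverage-based applicability-domain (Williams)
    diagnostics, variance inflation factors and descriptor mean effects.
    Includes a synthetic descriptor-matrix generator for benchmarking
    selection and validation behaviour at realistic problem sizes.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
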