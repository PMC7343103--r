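Package: depscreen
Title: Dielectrophoretic Spectrum Analysis for Label-Free Cancer Screening
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward modelling and diagnostic analysis of dielectrophoresis
    (DEP) spectra from well-plate cytometers. Implements the single-shell
    Clausius-Mossotti model of the cellular DEP response with crossover-
    frequency estimation and least-squares parameter fitting, simulation of
    two-arm clinical cohorts with instrument noise, dead-connection points
    and low-cell failures, spectrum processing (repeat medians, dead-point
    masking, arm averages), the Mean Difference Value (MDV) band statistic
    with a spectrum-standard-deviation exclusion filter, and diagnostic
    reporting (confusion matrices, sensitivity/specificity, two-sample
    t-tests, threshold sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, minpack.lm, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
biocViews: Software, Classification, CellBiology
RoxygenNote: 7.3.3
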