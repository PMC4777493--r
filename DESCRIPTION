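Package: osascreen
Title: Nonlinear Respiratory Signal Analysis for Obstructive Sleep Apnea Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-support pipeline for obstructive sleep apnea (OSA)
    screening from overnight respiratory recordings. Reads and writes
    European Data Format (EDF) files; extracts nonlinear indices --
    detrended fluctuation analysis (DFA) scaling exponents, approximate
    entropy ApEn(m, r, N), and the largest Lyapunov exponent by the
    Rosenstein method -- together with the oximetry statistic T90 from
    nasal-cannula airflow, thoracic belt and SpO2 channels; predicts the
    apnea-hypopnea index (AHI) with a published linear equation; classifies
    severity; and induces C4.5-style gain-ratio decision trees evaluated by
    stratified 10-fold cross-validation. Includes a synthetic overnight
    recording generator with ground-truth event lists so that the entire
    pipeline can be exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite,
    nortest,
    deSolve
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
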