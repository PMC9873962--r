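Package: cardiomiR
Title: Plasma miRNA Screening, Cardiac Energetics and Survival Analysis
    for Myocardial Infarction Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing plasma miRNA microarray profiles from
    myocardial infarction cohorts stratified by heart-failure status.
    Implements single-channel array preprocessing (technical-replicate
    averaging, an inclusive intensity floor, per-sample median
    normalization), a differential-miRNA screen with data-driven test
    selection (Student/Welch t, ANOVA/Welch ANOVA), linear fold changes,
    volcano-plot coordinates and top-k ranking tables; echocardiographic
    energetics indices (LVEF, left ventricular mass, body surface area,
    circumferential end-systolic wall stress and myocardial energy
    expenditure); Kaplan-Meier product-limit estimation with a log-rank
    comparison of expression-defined patient groups; and a synthetic
    cohort simulator with planted fold changes, group-dependent
    echocardiographic parameters, exponential survival and cell-viability
    trajectories so every pipeline stage is testable against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    car,
    jsonlite
Suggests:
    withr,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
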