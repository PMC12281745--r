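Package: pbmcsig
Title: Minimal PBMC Immune-Signature Discovery for Second-Line Treatment
    Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for discovering minimal immune-cell
    signatures in peripheral blood mononuclear cell (PBMC) profiling data
    and using them to predict dichotomized clinical outcomes such as
    time-to-treatment-failure under second-line chemotherapy.  Covers
    event-level flow-cytometry feature extraction (sequential pre-gating,
    manual rule gates, and automated Gaussian-mixture "HyperGating"
    meta-clustering), RT-qPCR delta-Ct normalization, clinical-ratio
    engineering, three feature-selection strategies (statistical ranking,
    PCA-based ranking, and classifier-driven bidirectional wrapper search
    plus a hybrid), a classifier bench built around kernel logistic
    regression with naive Bayes, logistic regression and ZeroR baselines,
    repeated stratified cross-validation and bootstrap performance
    testing with class-averaged metrics, and the survival statistics used
    for feature interpretation (Kaplan-Meier/log-rank, Cox proportional
    hazards, Spearman matrices, normality-gated group tests, and
    FDR-based robust outlier detection).  A seeded synthetic-cohort
    generator with planted population-frequency effects and
    proportional-hazards outcomes makes every stage testable without
    access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    mclust,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
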