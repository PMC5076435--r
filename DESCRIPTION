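Package: longconn
Title: Longitudinal Functional Connectome Analysis with Sparse Partial
    Correlation Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for longitudinal resting-state functional connectivity
    analysis of small clinical cohorts scanned repeatedly around a focal
    intervention (e.g. unilateral thalamotomy for essential tremor). Covers
    temporal preprocessing of region-level BOLD time series (eigenvariate
    extraction, nuisance and trend regression, discrete-cosine high-pass),
    construction of Pearson/Fisher-z functional connectivity and sparse
    partial-correlation networks via the graphical lasso with StARS penalty
    selection and a covariance-selection refit that removes L1 shrinkage,
    weighted graph metrics (degree, strength, nodal path-length, global
    efficiency, inter-hemispheric similarity), and a longitudinal statistical
    layer (repeated-measures ANOVA with Greenhouse-Geisser and Huynh-Feldt
    corrections, Tukey HSD, Benjamini-Hochberg FDR, random-intercept linear
    mixed models). A synthetic-cohort generator draws BOLD-like series from
    ground-truth Gaussian graphical models with programmable persistent and
    transient lesion effects and coupled ordinal tremor scores, so every
    stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    lme4,
    lmerTest,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
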