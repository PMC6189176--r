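Package: sustainr
Title: Subtype and Stage Inference for Cross-Sectional Biomarker Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised modelling of disease heterogeneity from purely
    cross-sectional biomarker measurements. Subjects are simultaneously
    clustered into subtypes and placed along each subtype's progression
    timeline using an event-based mixture model in which every biomarker
    follows a piecewise-linear z-score trajectory. Includes greedy
    expectation-maximisation fitting with hierarchical cluster splitting,
    Markov chain Monte Carlo uncertainty estimation over event orderings,
    cross-validated model selection via an information criterion,
    per-subject subtyping and staging, control-referenced z-score
    preprocessing, comparator subtypes-only and stages-only models, and a
    ground-truth cohort simulator for validation studies.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    mclust,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
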