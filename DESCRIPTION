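Package: ebmHD
Title: Event-Based Modelling of Biomarker Progression in Huntington's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers the order in which regional brain-volume biomarkers
    become abnormal in Huntington's disease from cross-sectional data,
    using a probabilistic event-based model. Provides covariate correction
    and data-driven biomarker selection, per-biomarker Gaussian mixture
    models with a fixed control component, maximum-likelihood event
    sequence estimation with MCMC uncertainty quantification (positional
    variance diagrams), cross-sectional patient staging, bootstrap
    cross-validation of the sequence, and longitudinal, conversion and
    phenotype validation analyses. Includes a synthetic cohort generator
    that emulates the assumed monotonic staged progression so the whole
    pipeline can be exercised without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
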