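Package: germtherm
Title: Population-Based Thermal-Time Threshold Modelling of Seed Germination
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Forward simulation and inverse fitting of population-based
    thermal-time threshold models for seed germination time-courses, with
    dormancy-layer decomposition, gibberellin/abscisic-acid metabolite
    bookkeeping and efficiency-corrected RT-qPCR normalization with
    geNorm-style reference-gene stability ranking. Developed around the
    dimorphic (black/brown) seeds of the weed Chenopodium album: cardinal
    temperatures (base, optimal, ceiling) and normally distributed
    thermal-time thresholds are recovered from replicate petri-dish
    germination assays by percentile-wise two-regime linear regression of
    germination rate on temperature followed by probit fits of the
    threshold distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Regression, TimeCourse, GeneExpression, Normalization
RoxygenNote: 7.3.3
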