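Package: starchnet
Title: Diurnal Transcriptional Network Inference for Starch Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers transcriptional regulatory networks for diurnal starch
    metabolism from small time-course expression experiments. Provides
    spline-based time-course significance testing with permutation p-values
    and Storey q-values, k-means profile clustering with light/dark response
    group assignment, small-sample graphical Gaussian model inference via
    shrinkage partial correlation with empirical-null mixture-model edge
    calibration, subnetwork and hub analysis, candidate-regulator ranking
    against condition-independent co-expression compendia, Mann-Whitney
    morphometrics for chloroplast and starch-granule measurements, and
    synthetic-data generators with known ground truth for validating every
    stage of the pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    splines,
    igraph,
    MASS,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
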