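Package: conncompare
Title: Integrated Group Comparison of Structural and Functional Brain
    Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds region-pair brain connectivity networks from functional
    time series (Pearson and partial correlation) and from voxel cost images
    (minimum-cost-path cost and path-averaged fractional anisotropy), and
    compares them between two subject groups. Provides per-edge ordinary
    least squares statistics with covariate adjustment, a Bonferroni
    correction based on the effective number of independent tests estimated
    from the eigenvalues of the between-edge correlation matrix, one-sample
    shift tests for lobe-pair clusters of edges, and deterministic plot-data
    builders for worm plots, connectograms and bi-modal comparison plots.
    A synthetic two-group cohort generator with known ground truth supports
    calibration and power evaluation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    ggplot2,
    rlang,
    yaml,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
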