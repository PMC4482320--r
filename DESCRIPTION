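Package: voxcent
Title: Voxel-Wise Degree and Eigenvector Centrality Analysis of Masked fMRI Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for voxel-wise functional-network centrality analysis of
    resting-state fMRI within a binary network mask: temporal and spatial
    preprocessing (volume discarding, ideal band-pass filtering, Gaussian
    smoothing, nuisance regression, head-motion QC), thresholded weighted
    degree centrality computed in column blocks, matrix-free eigenvector
    centrality by power iteration on the shifted correlation matrix,
    rank-Gaussian and global-mean map normalization, voxel-wise group
    inference (two-sample, paired, and ANCOVA general linear models with
    covariates), Monte-Carlo cluster-size correction in the AlphaSim style,
    morphometric measures (brain parenchymal fraction, lesion load), and
    cluster-level clinical regression with Bonferroni correction. A seeded
    synthetic-data generator produces masked 4D time series with known
    hub/community structure, group effects, paired sessions, clinical
    covariates, motion traces, and segmentation volumes so every pipeline
    stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
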