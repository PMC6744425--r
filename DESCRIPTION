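Package: ndbar
Title: Neural Distance-to-Bound Analysis for Multivoxel Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for relating categorization behavior to the geometry of
    multivoxel activation patterns. Implements regularized linear discriminant
    decoding with signed decision-boundary distances, volume-based searchlight
    mapping with false-discovery-rate control and top-percentile voxel
    selection, LISAS speed-accuracy integration of reaction times, per-category
    distance-behavior correlation with group inference, a percentile-summed
    (city-block) combination of distances for category structures that
    crisscross two stimulus dimensions, split-half reliability with
    Spearman-Brown correction and joint noise ceilings, GIST image descriptors
    for low-level stimulus controls, and a seeded synthetic-data generator that
    emulates the assumed study design end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
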