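Package: cooccurspat
Title: Co-Occurrence Null Models and Spatially Explicit Occupancy Analysis for
    Soil Animal Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying biotic interactions in site-by-species
    data against spatially structured environments. Implements the C-score
    and SIM9 fixed-fixed swap randomization with standardized effect sizes
    and empirical-Bayes pairwise segregation/aggregation tests; binomial
    occupancy regression with residual spatial correlation fitted by
    penalized quasi-likelihood with a spherical correlogram; Moran's I
    correlograms; principal coordinates of neighbour matrices (PCNM/db-MEM)
    with AIC forward selection; Hellinger-transformed redundancy analysis
    with three-set variance partitioning and residual cross-species
    correlations; and a Gaussian-random-field landscape simulator for
    end-to-end calibration and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
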