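Package: cellswarm
Title: Learning Anisotropic Cell-Cell Interaction Rules from Individual
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies directional pairwise interaction rules
    (attraction-repulsion, alignment, drag) for every cell in a
    heterogeneous migrating population from trajectory data alone.
    Single-cell force models are learned by weak-form sparse regression
    with physical sign constraints, cross-pollinated between
    statistically similar cells, clustered by their active directional
    force modes, averaged into candidate species models, validated by
    fast data-driven forward simulation, and sorted into species with a
    two-component Gaussian mixture on log validation errors.  Includes
    the second-order interacting-particle simulator used to generate
    benchmark populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mclust,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
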