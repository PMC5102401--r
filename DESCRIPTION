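Package: reefprior
Title: Factorial Reserve-Selection Experiments on Synthetic Reefscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how planning-unit size, thematic resolution of
    reef classes, and spatial variability of socioeconomic cost interact to
    shape marine conservation priorities. Generates synthetic raster
    reefscapes with a five-level hierarchical reef classification, builds
    nested square planning-unit grids clipped to reef, solves Marxan-style
    minimum-set reserve-selection problems with simulated annealing and
    iterative improvement, runs the full 2 x 5 x 2 factorial of
    prioritisation scenarios with species-penalty-factor calibration, and
    analyses the resulting solutions as community data: Hellinger
    transformation, Euclidean dissimilarity, average-linkage clustering,
    redundancy analysis with a permutation test, spatial nestedness of
    fine-resolution priorities in coarse ones, and expected incidental
    representation of fine reef classes with their rarity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
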