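Package: sweepscan
Title: Selective Sweeps, F_ST Outliers, and the Footprint of Global Adaptation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward-in-time simulation and genome-scan machinery for studying
    how species-wide ("global") adaptation generates F_ST outliers that mimic
    local adaptation. Provides a two-deme Wright-Fisher simulator with
    selection, recombination and migration; windowed Weir-Cockerham F_ST,
    within-population diversity (pi_W) and between-population diversity (d_XY)
    scans; neutral-null outlier calling with lag/Bierne/drift classification
    and bootstrap rates; and closed-form diffusion calculators for sweep
    timescales, fixation probabilities and the adaptive proportion of
    substitutions (alpha) under an exponential distribution of fitness
    effects.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
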