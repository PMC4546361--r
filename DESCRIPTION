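Package: driftpainter
Title: Drift-Aware Chromosome Painting and Ancestry-Profile Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Distinguishes recent-isolation ("marginalisation") from
    ancient-split ("remnants") population histories using haplotype
    painting under a Li-and-Stephens copying model. Provides a
    ChromoPainter-style copying HMM with configurable donor sets,
    non-negative least-squares cleaning of copying vectors into ancestry
    proportions with weighted block-jackknife standard errors, drift-scaled
    profile-distance statistics (TVD, F_XY, P(X)), Dirichlet-multinomial
    Gibbs clustering of copied-length vectors, two-source local-ancestry
    segment calling with allele-match similarity and introgression ratio
    tests, coancestry-curve construction with exponential admixture dating,
    and a coalescent synthetic-data generator (splits, bottlenecks,
    migration pulses, SNP ascertainment, admixture mosaics) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    yaml,
    pracma,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
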