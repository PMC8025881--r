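Package: cryoseqid
Title: Protein Identification from Cryo-EM Maps by Side-Chain Density Matching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies which protein from a candidate sequence database is
    present in a cryo-EM density map, given a sequence-free backbone trace.
    Builds per-segment position-specific scoring matrices from best-rotamer
    map-model correlations converted to non-negative Z-scores, aligns
    candidate sequences in a six-letter reduced amino-acid alphabet with
    affine-gap dynamic programming, adjusts scores against a random-sequence
    null, and ranks the database by Z-score. Includes an idealized and a
    learnable rotamer density template library, side-chain refitting onto the
    backbone, MRC/CCP4 map input and output, and a synthetic-fixture
    generator (Gaussian-atom maps, trace-like backbone perturbations, decoy
    databases) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    Biostrings,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
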