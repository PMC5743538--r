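Package: nvphylo
Title: Alignment-Free Phylogenetics with Covariance-Extended Natural Vectors
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Alignment-free comparison of DNA and protein sequences via the
    natural vector representation (per-symbol counts, mean positions, and
    normalized second central moments of positions) extended with positional
    covariances for every unordered symbol pair (18 dimensions for DNA, 250
    for protein).  Organisms represented as sets of sequences (e.g. whole
    ribosomal proteomes) are compared with the Hausdorff distance between
    their natural-vector sets; phylogenies are reconstructed by
    single-linkage clustering with bootstrap clade support, and sequences
    are assigned to taxa by leave-one-out nearest-neighbor classification.
    Includes a k-mer composition baseline, a planted-clade synthetic strain
    simulator for offline validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    igraph,
    ape,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
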