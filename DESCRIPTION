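Package: fisheggs
Title: DNA-Barcoding Identification and Spawning Phenology of Drifting Fish Eggs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification of drifting fish eggs and larvae from COI DNA
    barcodes against a local reference library, and summarisation of the
    resulting egg-pool community through time. Implements exhaustive
    semi-global similarity search with percent-identity ranking, a
    hierarchical threshold-based assignment cascade (species, genus,
    unidentified, with best/second-best and top-hit consensus rules),
    Kimura two-parameter distances, neighbor-joining trees with bootstrap
    supports, single-linkage lineage delimitation at a divergence
    threshold, and taxon-by-month occurrence, richness and spawning-period
    summaries. A sequence-survey simulator with a configurable barcoding
    gap, species-specific spawning windows and amplification dropout
    supports validation of the whole pipeline against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    ape,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
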