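Package: mitewave
Title: Archaeology of MITE Amplification Bursts in Genomes
Version: 0.1.0
Authors@R:
    person("Repeat", "Archaeology Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to reconstruct the history of miniature inverted-repeat
    transposable element (MITE) families from homology-search output.
    Provides per-position query-coverage profiles with deletion-drop
    detection, defragmentation of fragmented hits into element copies,
    majority-rule consensus building, Jukes-Cantor divergence landscapes,
    substitution-rate calibration and activity dating via T = D/s,
    genic-context classification with chi-square independence tests, and
    dissection of composite elements into terminal inverted repeats and
    parental homology segments. A seeded synthetic-burst genome simulator
    with full ground truth makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
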