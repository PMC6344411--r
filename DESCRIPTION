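Package: codhscan
Title: Structural Classification and Genomic-Context Analysis of Anaerobic Ni-CODHs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies anaerobic nickel-containing carbon-monoxide
    dehydrogenases (Ni-CODHs) of the hybrid-cluster protein family into
    seven clades and 24 structural groups from the cysteine/histidine
    signatures of their metal clusters (D-, B-, C-, E- and F-clusters) and
    acid-base catalytic residues.  Extracts CODH-anchored directons
    (same-strand gene runs) from gene coordinate tables, tests COG
    annotations for enrichment inside those directons with a one-sided
    Fisher exact test under Benjamini-Hochberg false-discovery-rate
    control, and builds a Simpson-coefficient co-occurrence network
    linking COGs, structural groups and taxonomies.  Ships a seeded
    synthetic-data generator that plants known motif signatures and
    genomic contexts so the whole pipeline is testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
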