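Package: phylodelim
Title: Genome-Based Taxonomic Delimitation with Whole-Genome Similarity
    Indexes and Distance Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes the pairwise genome similarity indexes used for
    prokaryotic taxonomy (fragment-based average nucleotide identity,
    average amino acid identity over reciprocal best hits, percentage of
    conserved proteins, genome-BLAST-style distances and digital DNA-DNA
    hybridization), infers distance-based whole-genome phylogenies with
    pseudo-bootstrap support, and delimits monophyly-constrained genus and
    species clusters with nomenclature-priority name resolution. Includes a
    synthetic genome/proteome simulator with planted taxonomy so the whole
    pipeline can be validated against known truth, and an end-to-end
    pipeline driver with resumable steps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    Biostrings,
    jsonlite,
    phangorn,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
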