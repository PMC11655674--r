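Package: qsmotif
Title: Discovery of Quorum-Sensing Transcription-Factor Binding Sites in
    Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("qsmotif", "developers", email = "qsmotif@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for the in-silico discovery of the DNA
    binding site of a LuxR-family quorum-sensing regulator. Starting from a
    differential-expression table, the pipeline subtracts a prior regulon,
    collapses genes into transcriptional units by an intergenic-distance
    rule, extracts promoter windows, harvests ortholog promoters by
    reciprocal best hits with an affine-gap local aligner, learns a position
    weight matrix by zero-or-one-occurrence-per-sequence (ZOOPS)
    expectation-maximization, scans candidate regulatory regions with exact
    p-values computed by dynamic programming over the score distribution,
    and summarizes palindromic double hits. Degenerate IUPAC motif algebra,
    a domain-score classifier for LuxR/LuxI homologs, and seeded synthetic
    data generators (genomes, DE tables, planted motif sites, diverged
    ortholog promoter families, artificial promoter constructs) make every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
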