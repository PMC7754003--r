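Package: abseqpipe
Title: Single-Cell Multi-Omics (AbSeq + Targeted mRNA) Read Processing and
    Cohort Proportion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing pipeline for paired-end single-cell multi-omics reads
    in which R1 carries a three-section cell label, a unique molecular
    identifier (UMI) and a poly(T) tail, and R2 carries a fragment of a
    targeted mRNA or antibody-tag panel. Implements read-level quality
    filtering, positional cell-label annotation with substitution and indel
    recovery against 96-sequence whitelists, seed-and-extend panel alignment
    with uniqueness and decoy validity rules, UMI molecule collapsing with
    recursive substitution error correction (RSEC) and distribution-based
    error correction (DBEC), knee-point cell calling on the cumulative read
    curve, sparse count-matrix export, and case versus control
    cluster-proportion statistics. Includes a paired-FASTQ simulator with
    per-read ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
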