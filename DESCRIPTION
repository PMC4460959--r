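Package: enhancerlink
Title: Linking Cancer-Altered Distal Enhancers to Target Genes and Upstream
    Transcription Factors from Methylation and Expression Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Infers cancer-altered distal enhancers from paired Infinium-style
    DNA methylation (beta values) and gene-level expression matrices. Calls
    hypo-/hypermethylated enhancer probes by comparing extreme methylation
    quintiles of tumor versus normal samples, links differentially methylated
    probes to putative target genes among the twenty nearest transcription
    start sites using one-sided Mann-Whitney tests with permutation-based
    empirical p-values, scans probe-flanking sequence for transcription factor
    binding motifs with an exact score p-value engine, tests motif enrichment
    with odds-ratio confidence bounds, and ranks candidate upstream regulator
    transcription factors by anti-correlation of their expression with
    motif-adjacent methylation. Includes a seeded synthetic-cohort generator
    with truth tables so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
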