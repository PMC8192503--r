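Package: edscape
Title: A-to-I RNA Editing Landscape Analysis with Planted-Truth Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for genome-wide adenosine-to-inosine (A-to-I) RNA-editing
    analysis from matched DNA and RNA alignments: filtered pileup
    construction, recovery of hyper-edited reads by base-transformed
    realignment, two-round editing-site identification with homozygosity,
    evidence, paralog and multi-sample filters, genic/repeat/recoding
    annotation, editing-level statistics (pooling, overall editing,
    clustering tendency, PCA, size-factor normalization), region-specificity
    classification, miRNA seed-site alteration prediction, and cross-species
    differential editing by Fisher's exact test. Includes a synthetic-data
    generator that plants editing sites, heterozygous SNP confounders,
    sequencing errors, PCR duplicates and hyper-edited reads with full ground
    truth, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    rtracklayer,
    yaml
Config/testthat/edition: 3
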