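Package: promevol
Title: Promoter Evolution Hotspots and Expression Divergence in
    Accessory Gland Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying rapid promoter evolution of
    tissue-specific genes across closely related Drosophila species.
    Implements the graded tissue-specificity index tau for gene-set
    selection, CAGE-based dominant transcription start site calling via
    a nine-nucleotide sliding window score, 0/1 event coding of
    multi-species promoter alignments (base changes and indels against a
    reference species), five-base sliding event scores with
    control-baseline hotspot scores (d) and PhyloP-based analogues
    (d^P), G-function detection of positional substitution hotspots with
    a Monte Carlo null, and an expression-divergence layer linking
    promoter scores to species and hybrid-allele expression changes.
    Includes a synthetic-data generator that emulates all external
    inputs with known truth, so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
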