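Package: fusionlite
Title: Fusion Gene Detection from Paired-End RNA-Seq by K-mer Quasi-Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects fusion genes from paired-end RNA-seq reads by
    quasi-mapping read pairs to a k-mer transcriptome index, extracting
    discordant (junction-spanning) read pairs and split reads, grouping
    spanning pairs into fusion equivalence classes with
    multiplicity-corrected fragment counts, calling exact junction
    breakpoints from split reads, and applying a cascade of filters
    (general gene features, sequence similarity, positional
    distribution) before scoring and ranking candidates. Includes a
    synthetic transcriptome/fusion/read simulator for validation and
    the evaluation statistics (recall, precision, F1, Fisher exact
    precision comparisons, operating-characteristic curves) used to
    benchmark fusion callers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    Rcpp,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
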