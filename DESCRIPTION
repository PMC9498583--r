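Package: natheat
Title: Discovery and Heat-Stress Analysis of Cis-Natural Antisense Transcript Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A strand-aware pipeline for identifying long non-coding RNAs and
    cis-natural antisense transcript (NAT) pairs from transcript models, and
    for characterising their behaviour under heat stress. Classifies lncRNA
    candidates (lincRNA, intronic RNA, antisense), discovers cis-NAT pairs by
    opposite-strand span overlap, orients and classifies pairs (enclosed,
    convergent, divergent), calls heat-responsive pairs from replicated TPM
    expression with fold-change and significance thresholds, splits pairs into
    concordant and discordant by fold-change correlation, flags nat-siRNA
    precursor candidates from small-RNA alignments in pair overlap regions,
    computes TSS-anchored histone-mark and DNA-methylation profiles, and scans
    promoters for canonical and non-canonical heat-shock elements. Ships a
    fully parameterised synthetic-data generator with a machine-readable truth
    table so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    dplyr,
    tibble,
    tidyr,
    readr,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
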