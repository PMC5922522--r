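Package: cnvlossr
Title: Validation of Copy-Number-Loss Calls by Concordance, Read Depth and
    Breakpoint Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to validate candidate copy-number-loss (deletion) calls
    against independent evidence. Implements cross-callset concordance under
    a directional 50 percent base-pair overlap rule with probe-count and
    gene-region filters, statistical testing of per-base read depth in
    candidate regions against chromosome-wide or flanking background (a
    two-sample chi-square test on binned depths and a permutation test on
    mean depth), and breakpoint discovery by local de Bruijn assembly of
    flank-covering and unmapped reads followed by anchored split alignment
    of contigs and paired-end insert-size evidence. A synthetic-data module
    simulates a reference, planted homozygous and heterozygous deletions,
    paired-end alignments at low depth, probe grids and discordant callsets
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    Rsamtools,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    readxl,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
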