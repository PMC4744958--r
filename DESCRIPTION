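Package: rtdkit
Title: Construction and Validation of Nonredundant Reference Transcript Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to merge transcript annotations from multiple sources (GTF
    and GFF3) into a nonredundant reference transcript dataset (RTD) for
    alignment-free transcript quantification. Gene-model spans are reconciled
    across sources, redundant transcripts are removed by intron-chain
    comparison (UTR-length variants of a shared intron chain, overlapping
    mono-exon variants, and low-coverage transcript fragments), and curated
    transcripts can be merged in with protection from removal. Companion
    functions compute dataset summary statistics (transcripts per gene,
    alternative-splicing frequency), quantify alternative-splicing event
    ratios from transcript abundances (TPM) and from RT-PCR peak areas, and
    correlate the two measurements. A deterministic synthetic-data generator
    produces genomes, redundant annotation pairs with known ground truth, and
    paired abundance/peak tables for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
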