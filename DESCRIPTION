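Package: weanlnc
Title: Long Non-Coding RNA Discovery and Cis-Target Co-Expression for
    Two-Timepoint Ruminant RNA-Seq Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native reimplementation of a bulk RNA-seq long
    non-coding RNA (lncRNA) analysis cascade for two-timepoint
    (pre-/post-weaning) designs in gastrointestinal tissues: transcript
    class-code comparison against a reference annotation, coding-potential
    scoring (ORF, Fickett TESTCODE, hexamer usage, logistic combiner) with
    ingestion of external CNCI/CPAT/BLAST evidence, median-of-ratios
    normalization, negative-binomial Wald differential expression with
    Benjamini-Hochberg correction, 50 kb windowed lncRNA-mRNA cis-target
    co-expression, hypergeometric gene-set enrichment, and 2^-ddCt qPCR
    validation. A synthetic-data generator with planted ground truth makes
    every stage testable without external downloads.
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
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr,
    broom
Config/testthat/edition: 3
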