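Package: stressnet
Title: Co-Expression Modules and Network Plasticity in Abiotic-Stress
    Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for time-course abiotic-stress microarray
    transcriptomes: permutation-based differential expression calling in the
    style of Significance Analysis of Microarrays (SAM), weighted gene
    co-expression network construction with topological-overlap module
    detection and module-level stress-response calls, differential-correlation
    ("network plasticity") analysis of transcription-factor/target pairs with
    a permutation-calibrated FDR cutoff, exhaustive short-motif (5-8 nt)
    promoter enrichment against a genome-wide background, and permutation
    gene-set overlap tests. Includes a fully specified synthetic-data
    generator emulating a four-stress, five-timepoint, triplicate design so
    that every stage is testable with known ground truth.
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
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
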