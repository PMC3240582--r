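Package: chipscore
Title: Multi-Mapping-Aware ChIP-Seq Bin Scoring, Noise Normalization, and
    Promoter Chromatin Analytics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic 50-bp bin scoring of ChIP-seq tags with
    fragment-length-derived tag extension, in unique-only (U) or
    1/k-weighted unique-plus-multiple (U+M) mode; sequencing-depth scaling,
    histogram-based noise normalization, background subtraction, and
    empirical false discovery rate thresholding of enrichment calls;
    genomic-feature and transposon-class score distribution analyses;
    expression-stratified metagene profiles around transcription start and
    end sites; RNA polymerase II stalling classification, strand-resolved
    5-bp positioning, and splice-junction occupancy profiles; TSS
    chromatin-signature clustering and a small feed-forward network that
    predicts expression from promoter chromatin state. Includes a
    synthetic-data generator (genome, annotation, expression, mark-specific
    tag sets with planted truth) so every stage is testable without
    external downloads, and an iterative best-tier read mapper that records
    mapping multiplicity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
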