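Package: tidychip
Title: Tidy Analysis of Protein Occupancy from ChIP Tiling Arrays and
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A tidyverse-native toolkit for genome-wide protein occupancy
    analysis in compact genomes such as fission yeast. Turns Affymetrix-style
    perfect-match/mismatch tiling-array probe intensities into per-gene and
    per-probe normalized ChIP signals, calls enriched genes with a robust
    sliding-window statistic and a fraction-of-gene rule, builds per-base
    input-normalized ChIP-seq coverage and two kinds of metagene profile,
    correlates occupancy with expression, classifies genes by the ratio of two
    ChIP signals, tests gene-set overlaps by permutation and by the
    hypergeometric tail, and provides the small closed-form qPCR
    quantifications (2^-dCT, percent of input, decay half-life). A
    synthetic-data module generates annotations, probe arrays, reads,
    expression tables and differential-expression labels with planted, recorded
    ground truth so that every stage of the pipeline is verifiable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
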