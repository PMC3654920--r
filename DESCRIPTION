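Package: trnahalves
Title: Discovery and Quantification of Circulating 5' tRNA Halves from Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of the serum small-RNA analysis that
    detects circulating 5' tRNA halves: a synthetic reference builder with
    multi-copy tRNA gene families, a ground-truthed FASTQ read simulator,
    adapter trimming and quality filtering, a deterministic seed-based
    short-read aligner exposing the two alignment policies and two
    multiread-reporting policies whose interplay reveals the 30-33 nt peak,
    feature annotation with 5'/3'-end classification and anticodon-relative
    cleavage-site profiling, and negative-binomial GLM likelihood-ratio
    testing of age and calorie-restriction contrasts with CPM filtering and
    signed fold changes. All stages take and return tidy tables and compose
    into a single deterministic pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools,
    MASS,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
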