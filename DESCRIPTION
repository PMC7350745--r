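Package: cladescan
Title: Motif-Anchored Detection and Characterization of Expanded
    Transcription-Factor Clades
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for characterizing tandemly duplicated
    transcription-factor clades from genome sequence and expression data:
    position-frequency motif models built from seed proteins, six-frame
    motif-anchored scanning for unannotated paralogs with window extension
    to a target protein length, percent-identity matrices and
    neighbor-joining trees from progressive multiple alignment, a promoter
    cis-regulatory element census over IUPAC patterns, topological-overlap
    co-expression neighborhoods intersected across expression series, and
    clade expression summary statistics. Includes a synthetic-data
    generator with known ground truth so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
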