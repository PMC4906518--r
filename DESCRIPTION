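Package: cfchimera
Title: Donor Chimerism and Fragmentomics of Ultrashort Cell-Free DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of plasma cell-free DNA (cfDNA) across nuclear,
    mitochondrial and microbial compartments. Builds per-subject
    mitochondrial consensus sequences from pileups and derives
    donor/recipient informative SNPs; assigns individual cfDNA fragments
    to transplant donor or recipient and estimates donor fractions with
    sample-level quality filters; profiles fragment lengths and GC content
    including a resampling median-shift statistic for donor versus
    recipient fragment size; models digital-PCR abundance as a function of
    amplicon length under random fragmentation to recover underlying
    fragment-length parameters and genome-equivalent copy ratios; and
    compares microbial relative genome coverage between single-stranded
    and double-stranded library preparations. A synthetic-data generator
    with planted ground truth makes every stage testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    dplyr (>= 1.1.0),
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
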