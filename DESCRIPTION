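Package: bescan
Title: Base-Editing Saturation-Mutagenesis Screen Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and analysing CRISPR base-editing
    saturation-mutagenesis screens of a single gene. Predicts adenine- and
    cytosine-base-editor outcomes for NGN-PAM guide libraries (individual and
    combined bystander edits), classifies protein and splice consequences
    against a gene model, turns raw sgRNA count tables into filtered,
    replicate-averaged, z-scored depletion measurements, projects guide scores
    onto protein residues to map essential regions, tests domain and
    pathogenicity-class hit enrichment, and quantifies cross-screen
    concordance. A negative-binomial screen simulator with ground-truth
    effects makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
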