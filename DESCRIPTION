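Package: triticolor
Title: ISBP Marker Anchoring, Haplotype Block Painting and Assembly QC for Polyploid Genome Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of chromosome-scale plant genome
    assemblies in a cultivar panel. Designs insertion site-based polymorphism
    (ISBP) junction markers from transposable-element annotations, anchors
    scaffolds into pseudomolecules by marker-pair collinearity against a
    reference, paints chromosomes into haplotype blocks with a coloured
    canonical k-mer index, detects introgressions from minority haplotype
    profiles corroborated by donor-read coverage, and computes assembly
    quality statistics (N50/NG50 family, exon and marker conservation,
    telomere arrays, k-mer consensus quality values). Includes a synthetic
    panel generator with machine-readable truth tables so every stage can be
    validated against planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    withr,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
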