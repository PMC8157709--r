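Package: suckerscreen
Title: Axillary-Meristem Expression Screening and Subgenome-Aware RNAi
    Trigger Design for Allotetraploid Tobacco
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for finding and validating
    lateral-shoot (sucker) suppression genes in allotetraploid tobacco.
    Implements an axillary-meristem RPKM fold-enrichment screen, a
    subgenome-aware RNAi hairpin trigger designer that maximises
    homoeolog (S/T) identity while discriminating against same-family
    paralogs, an exact 22-nucleotide off-target scanner over a
    transcriptome, and relative-to-null-segregant phenotype statistics
    that call effective suppression genes.  A synthetic-data generator
    emulates homoeolog pairs at controlled identity, expression tables
    with planted enrichment, and phenotype trials with known construct
    effects, so every stage is testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    withr
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
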