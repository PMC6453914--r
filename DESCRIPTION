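Package: hybmode
Title: Inheritance-Mode Classification and Allele-Specific Expression in F1 Hybrid Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing transcriptome inheritance in F1 hybrids and
    their pure-bred parents from RNA-seq read counts. Implements total-count
    percentage normalization with replicate averaging and Z-chromosome/zero
    filters, six-way inheritance-mode classification (conserved, additive,
    Cor-dominant, WL-dominant, over-dominant, under-dominant) under a
    symmetric 1.25-fold similarity rule, allele-specific expression analysis
    of dominant genes via log-ratio regression, read-depth filtering of
    breed-diagnostic SNPs and substitution into parental pseudo-genomes,
    cross-group consolidation with Venn partitions and nonparametric
    category-count tests, and a negative-binomial synthetic-data generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    methods,
    stats,
    utils,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
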