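Package: dielclust
Title: Diel Time-Course Expression Selection, Clustering and GO
    Overrepresentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for bulk RNA-seq time courses sampled over a
    light/dark (diel) photoperiod. Selects temporally variable, highly
    expressed genes with the MeanNeighbor statistic (mean absolute
    difference between consecutive time points), normalizes each gene to
    relative expression (row z-scores), groups genes by Ward hierarchical
    clustering, tests Gene Ontology term overrepresentation per group with
    one-sided Fisher's exact tests under a fixed or adaptive p-value
    cutoff, and classifies single-gene temporal patterns (peak time, fold
    change, dark-to-dawn versus late-light shapes). Includes a seeded
    synthetic FPKM time-course generator with planted group structure,
    annotation enrichments and pattern classes, so that every stage of the
    pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
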