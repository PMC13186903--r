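Package: haplostrat
Title: Genetic-Background Stratification from SNP Haplotype-Block
    Allele-Sharing Distances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies experimental animal cohorts by genetic background
    using allele-sharing distances computed over 4-SNP haplotype blocks,
    classical multidimensional scaling, UPGMA clustering, and
    nearest-reference-panel breed assignment, then re-analyses proarrhythmic
    remodeling phenotypes (atrial fibrosis, electrophysiology, atrial
    fibrillation inducibility, qPCR fold changes) stratified by the assigned
    background.  Includes exact Mann-Whitney and Fisher tests, delta-delta-Ct
    fold changes, and a seeded synthetic two-breed cohort generator so the
    whole pipeline runs and is validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
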