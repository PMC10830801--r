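Package: metapharm
Title: Integrated Untargeted Metabolomics and Network Pharmacology Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable implementation of the serum-metabolomics
    plus network-pharmacology screening workflow used to nominate disease
    biomarkers and drug targets: LC-MS peak-table cleaning (retention-time
    window, detection-rate filter, half-minimum imputation, log10 transform,
    scaling), PCA and multiclass OPLS-DA with VIP scores, seven-fold
    cross-validated Q2 and a permutation validity test, a VIP / Mann-Whitney /
    recovery-trend / FDR screening cascade with fold-change reporting,
    formula-driven monoisotopic mass and adduct m/z annotation with diagnostic
    fragment checks, protein-protein interaction centrality screening of
    component and disease target sets, hypergeometric over-representation
    analysis, and 2^-ddCt relative-expression verification. A synthetic-data
    generator with planted ground truth replaces animals, instruments, and
    live web databases so every stage is reproducible offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    fgsea,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
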