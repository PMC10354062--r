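Package: ctdmod
Title: Rare Damaging Variant Modifier Analysis for Conotruncal Heart
    Defects in 22q11.2 Deletion Syndrome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Case-control analysis of rare, predicted most-damaging
    variants (MDRVs) as genetic modifiers of conotruncal heart defects in
    22q11.2 deletion syndrome. Provides variant-level quality control
    (genotype rate, exact Hardy-Weinberg test, excluded regions,
    cross-caller concordance), the MDRV filter cascade (gnomAD rarity,
    loss-of-function / damaging-missense / damaging-splicing
    classification, phastCons, CADD and CCRS thresholds), per-subject
    burden comparison, recurrent-gene selection with a cardiac-progenitor
    expression filter, hypergeometric over-representation analysis with
    Benjamini-Hochberg correction, an expression-weighted gene-set
    permutation test based on the quadratic form T = Z'JZ, gene-list
    overlap statistics, a seeded synthetic cohort generator, and an
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    withr
Config/testthat/edition: 3
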