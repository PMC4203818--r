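Package: cyp2d6star
Title: CYP2D6 Star-Allele Calling and Population Pharmacogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for CYP2D6 pharmacogenetic analysis of admixed
    cohorts genotyped on an eleven-variant TaqMan panel plus a whole-gene
    copy-number assay. Provides expectation-maximization haplotype phasing,
    perfect-match star-allele assignment, copy-number-aware diplotype
    assembly (whole-gene deletion *5 and xN duplications), predicted
    metabolizer phenotype classification (PM/IM/EM/UM), gene-counting
    frequency tables, two-level haplotypic AMOVA with permutation testing,
    Weir-Cockerham multi-allelic F_ST with bootstrap confidence intervals,
    contingency and rank-based association tests, and a synthetic
    admixed-cohort generator with per-individual Dirichlet ancestry that
    supplies ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
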