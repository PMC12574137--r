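Package: premdd
Title: Prematurity and Genetic Variation in Developmental Disorder Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how premature birth and genetic variation
    (monogenic diagnoses, de novo mutations, polygenic and rare-variant
    burden scores) jointly shape phenotypes in developmental-disorder
    cohorts. Provides ontology-aware phenotype derivation from HPO terms
    (descendant closures, non-redundant organ-system counts, LMS birthweight
    z-scores), a regression battery with inverse-variance-weighted
    meta-analysis and Bonferroni ledgers, Kaplan-Meier/log-rank and Cox
    models for developmental milestones, de novo mutation burden tests
    against a null mutational model with synonymous calibration and
    attributable fractions, gene and gene-set diagnostic enrichment tests,
    polygenic and rare-variant burden scoring with trio decomposition of
    direct and parental effects, and a synthetic cohort generator that
    emulates the statistical structure these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    survival,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
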