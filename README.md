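# premdd

Statistical tools for studying the interplay between **premature birth and
genetic variation in rare developmental disorders (DDs)**. Large
clinical-sequencing cohorts of children with DDs mix two major influences
on phenotype: rare damaging genetic variation (monogenic diagnoses, de
novo mutations) and environmental exposures, of which prematurity is among
the most common. `premdd` is aimed at statistical geneticists and
genetic-epidemiology analysts who need to ask, in such cohorts: does
prematurity broaden the clinical picture? Do prematurity and a monogenic
diagnosis act additively or multiplicatively? Is the burden of de novo
mutations — and the fraction of cases it explains — different in term and
preterm children? And are polygenic associations with gestational
duration direct effects of the child's genome or reflections of parental
alleles?

## What it computes

* **Ontology-aware phenotypes** — HPO descendant closures ("a term and its
  daughter nodes"), non-redundant organ-system counts (each term assigned
  to exactly one system), WHO prematurity categories (extreme < 28,
  very 28–31, moderate 32–36, term 37+ completed weeks), LMS birthweight
  z-scores `z = ((x/M)^L − 1)/(L·S)` with a 5-SD outlier filter.
* **Regression battery** — logistic / linear / negative-binomial models of
  each phenotype on the degree of prematurity with outcome-class
  covariates, diagnosis interactions, per-cohort fits pooled by
  fixed-effect inverse-variance weighting
  (`β = Σwβᵢ/Σw`, `w = 1/SE²`), and explicit Bonferroni ledgers
  (e.g. 0.05/522 = 9.58 × 10⁻⁵).
* **Milestone survival** — Kaplan–Meier + log-rank across gestational age
  groups; Cox proportional hazards (Efron ties) with
  prematurity-by-diagnosis interactions.
* **De novo mutation burden** — expected counts under a per-gene null
  mutational model, synonymous calibration
  `λ = O_syn / E_syn` over all probands, one-sided exact Poisson excess
  tests in 18 strata, and the attributable fraction

  ```
  AF = (O_nonsynonymous − λ·E_nonsynonymous) / N_probands
  ```

  with Poisson-count standard errors and term-vs-preterm z-tests.
* **Diagnostic enrichment** — per-gene logistic tests of prematurity among
  diagnosed probands (≥ 30-variant genes; ≥ 80% power for OR ≥ 6), exact
  Fisher tests of gene-set enrichment across gestational age groups with
  post hoc pairwise contrasts.
* **Genetic scores** — polygenic scores as weighted dosage sums with
  allele matching, a rare-variant burden score (high-confidence PTVs and
  MPC ≥ 2 missense-like variants in pLI > 0.9 genes, inherited, autosomal
  heterozygous, gnomAD MAF < 10⁻⁵, cohort MAF < 10⁻⁴), rank-based inverse
  normal transformation, score-on-gestation regressions with sex + 20 PCs
  and diagnosis interactions, and the trio decomposition separating direct
  (child) from non-transmitted (parental) polygenic effects.
* **Synthetic cohort generator** — seeded, substreamed simulators for
  cohorts, DNMs (with injectable gene-set excess), trios, milestone times
  and rare-variant tables, emulating the statistical structure the
  analyses assume so everything is testable without patient data.

## Worked example

```r
library(premdd)

cfg <- sim_config(n_probands = 5000, seed = 7,
                  dnm_excess = c(ddg2p = 0.25),
                  gene_sets = list(ddg2p = sprintf("G%04d", 1:20)))
cohort <- simulate_cohort(cfg)
cohort_summary(cohort)
#> Cohort of 5000 probands
#>
#> Gestational age group:
#>  category    n  pct
#>      term 4152 83.0
#>  moderate  698 14.0
#>      very  108  2.2
#>   extreme   42  0.8
#>
#> Diagnosed:
#>     group n_diagnosed  pct
#>       all        2072 41.4
#>      term        1780 42.9
#>  moderate         245 35.1
#>      very          36 33.3
#>   extreme          11 26.2
```

The simulated cohort reproduces the configured composition: ~84% term
probands and a diagnostic yield that declines with the degree of
prematurity. Now inject 0.25 excess nonsynonymous de novo mutations per
diagnosed proband into a 20-gene DD-associated set and run the burden
analysis:

```r
rates <- synthetic_gene_rates(n_genes = 100, seed = 7)
dnms <- simulate_dnms(cohort, rates, cfg)
burden <- run_dnm_analysis(cohort, dnms, rates)
burden$lambda
#> [1] 0.9738749
subset(burden$strata, proband_group == "all" & gene_set == "ddg2p")
#>  gestation n_probands observed expected excess_p     af  af_lo af_hi
#>       term       4152      874    473.6 1.19e-65 0.0994 0.0855 0.113
#>    preterm        848      177     96.7 1.87e-14 0.0977 0.0669 0.128
```

The synonymous calibration factor λ sits near 1 (the simulation obeys the
null mutational model), both gestational groups show a highly significant
nonsynonymous excess in the DD-associated genes, and the attributable
fraction in each group recovers the injected signal: 0.25 excess DNMs per
diagnosed proband × ~40% diagnosed ≈ 0.10 of cases attributable. The
term-vs-preterm z-test on these AFs is null by construction
(z = 0.10, p = 0.92), as reported in `burden$comparisons`.

A ready-made end-to-end configuration ships with the package
(`inst/extdata/example_config.yaml`, gene sets in
`inst/extdata/gene_sets.gmt`); run it with `run_pipeline()` or the thin
CLI at `inst/scripts/premdd`.

## Package layout

* `R/` — implementation: `ontology.R`, `phenotype.R`, `simulate.R`,
  `assoc.R`, `milestones.R`, `dnm.R`, `enrichment.R`, `scores.R`,
  `pipeline.R`.
* `vignettes/premdd-methods.Rmd` — the methods vignette: models,
  assumptions, parameter defaults, numerical choices, and what the
  synthetic generator does and does not emulate.
* `tests/testthat/` — unit, property and acceptance suites with
  independent brute-force oracles (closure enumeration, hypergeometric
  enumeration, hand-computed log-rank, closed-form arithmetic).
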