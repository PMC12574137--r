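---
title: "Methods: prematurity and genetic variation in developmental-disorder cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prematurity and genetic variation in developmental-disorder cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(premdd)
```

# Scope and model of the data

`premdd` implements the statistical machinery used to study how premature
birth and genetic variation jointly shape phenotypes in large
clinical-sequencing cohorts of children with rare developmental disorders
(DDs). A cohort is a table of probands with gestational age at birth
(completed weeks), a WHO prematurity category, sex, birthweight, ages,
Human Phenotype Ontology (HPO) annotations, monogenic diagnosis status, and
developmental-milestone attainment times. Around this table the package
provides five analysis layers — ontology-aware phenotype derivation, a
regression battery, milestone survival analysis, de novo mutation (DNM)
burden, diagnostic enrichment, and genetic-score models — plus a synthetic
cohort generator that emulates the statistical structure all of them
assume, so that every stage is testable without access-controlled patient
data.

Individual-level data from the real cohorts this methodology targets are
access-controlled, so the package makes no attempt to reproduce
cohort-specific effect sizes; its tests demonstrate calibration (null
behaviour) and parameter recovery (injected effects) on synthetic data, and
reproduce the analytically self-contained quantities (closed-form
thresholds, worked examples, exact-test oracles).

# Phenotype derivation

**Prematurity.** Delivery before 37 completed weeks is preterm, subdivided
by the WHO scheme: extreme (< 28 weeks), very (28 to < 32), moderate (32 to
< 37); 37+ is term. Input is validated to [22, 44] completed weeks;
fractional values are floored with a warning because the definition is in
completed weeks. `classify_prematurity()` partitions the range with no gaps
or overlaps (checked exhaustively in the tests).

**Closure queries.** Counting probands with "an abnormality of organ system
X" requires the query term *and all of its descendants* in the HPO
directed acyclic graph. `descendant_closure()` returns the term plus its
transitive descendants as a set, so multiple parentage never double-counts.
The OBO reader keeps only `is_a` edges and drops obsolete terms; other
relationship types carry no subsumption semantics for this purpose.

**Non-redundant organ-system counts.** HPO terms can descend from several
top-level systems, so naively counting systems per annotated term
over-counts. `assign_organ_systems()` maps every term to exactly one system
root. The published approach this mirrors does not print its
redundancy-resolution rule, so the package uses a deterministic,
documented stand-in: a term under several roots is assigned to the root
with the *smallest descendant closure* (the most specific system), with
remaining ties broken by lexicographic term ID; a user-supplied priority
list overrides both. `count_affected_systems()` is then the cardinality of
the distinct assigned roots over a proband's annotations, so a term and its
same-system ancestor contribute once.

**Birthweight z-scores.** Growth references are supplied in LMS form
(skewness L, median M, coefficient of variation S per sex and week):

$$z = \frac{(x/M)^L - 1}{L\,S}, \qquad |L| > 10^{-8};\quad
z = \frac{\log(x/M)}{S} \text{ otherwise.}$$

Lookup is exact on (sex, completed week) with no interpolation, keeping the
transform auditable. Probands with $|z| > 5$ are removed by
`filter_birthweight_outliers()` (count reported). The British 1990 growth
reference is licensed and cannot be redistributed, so the package ships a
clearly labelled *synthetic* LMS table
(`inst/extdata/lms_reference_synthetic.tsv`) whose median follows a
Hadlock-style log-quadratic fetal-weight curve with constant skewness
(L = 1) and CV (S = 0.11); real analyses should substitute a licensed
reference with the same columns.

# The regression battery

`fit_phenotype_model()` regresses each phenotype on the degree of
prematurity (three dummies against term, or standardised continuous
gestation) with outcome-appropriate families: logistic for binary
outcomes, linear for continuous, negative binomial for counts such as the
number of affected organ systems. Covariate sets follow the outcome class:
antenatal outcomes adjust for maternal age at birth; all other outcomes
adjust for the proband's age at assessment and sex. The interaction form
adds a diagnosis main effect and prematurity-by-diagnosis interaction to
ask whether a monogenic diagnosis modifies the prematurity association.
One extra covariate (deprivation index or a polygenic score) can be added
for sensitivity models.

Design notes:

* The negative binomial dispersion is estimated by maximum likelihood
  (`MASS::glm.nb`); if estimation degenerates the model falls back to
  Poisson with a warning, since the family choice should never silently
  change the battery's shape.
* Separation in logistic models is detected by diverging coefficients
  (|log OR| > 15 or SE > 100) and flagged `converged = FALSE` rather than
  Firth-corrected; inestimable terms (empty category cells) are reported
  with missing estimates, never dropped.
* Continuous gestation is standardised to mean 0, SD 1 *within cohort*
  (`standardise_gestation()`), so coefficients read per one-SD change.

Per-cohort estimates of the same term are pooled with fixed-effect
inverse-variance weighting (`ivw_meta()`): $w_i = 1/\mathrm{SE}_i^2$,
$\hat\beta = \sum w_i\beta_i / \sum w_i$,
$\mathrm{SE} = 1/\sqrt{\sum w_i}$. With only two cohorts a random-effects
model is not identifiable, so only the fixed-effect pool is offered. The
pooled SE can never exceed the smallest input SE (asserted as an
invariant).

Multiplicity is handled by explicit Bonferroni ledgers
(`bonferroni_threshold()`, `test_ledger()`); the canonical battery of 29
phenotypes x 3 prematurity levels x 6 model variants gives 522 tests and a
threshold of 9.58e-5.

# Milestone survival analysis

Time to attainment of developmental milestones (social smile, sitting,
walking, first words) is compared across gestational age groups with
Kaplan-Meier curves and k-group log-rank tests (`km_logrank()`), and
modelled with Cox proportional hazards (`cox_milestone_model()`) adjusted
for age, sex, diagnosis, and the prematurity-by-diagnosis interaction.
Ties are handled with the Efron approximation — ties are pervasive in
month-resolution milestone data and Efron is both standard and accurate
there. Hazard ratios below one mean slower attainment. The battery ledgers
are 0.05 divided by the number of milestones (log-rank) and by the number
of prematurity and interaction terms across milestones (Cox).

Milestone ages are analysed as entered. An optional
`correct_gestation = TRUE` toggle subtracts the gestational shortfall
relative to 40 weeks before analysis; it defaults off because milestone
data collected through questionnaires is often inconsistently
pre-corrected, and silently re-correcting would double-correct an unknown
subset. Degenerate inputs fail loudly: no events, groups without events,
or constant covariates are errors, and monotone-likelihood Cox fits are
flagged non-converged.

# De novo mutation burden and attributable fraction

Observed DNM counts are compared with the expectation of a null mutational
model supplied as a per-gene, per-class rate table
($\mu_{g,c}$, classes synonymous / missense / protein-truncating):
$E = N \sum_{g \in \text{set}} \sum_{c} \mu_{g,c}$. Because detection
pipelines deviate from any rate model, the expectation is calibrated with
the synonymous classes, assumed phenotypically neutral:

$$\lambda = \frac{O_\text{synonymous}}{E_\text{synonymous}}$$

computed once, exome-wide, over *all* probands, and reused across every
stratum. Excess of nonsynonymous DNMs is assessed with one-sided exact
Poisson tests, $p = P(X \ge O)$, in 18 strata: {term, preterm} x {all,
diagnosed, undiagnosed} x {exome, DD-associated (DDG2P), non-DDG2P},
with a 0.05/18 ledger. The attributable fraction — the proportion of cases
explained by nonsynonymous DNMs under the at-most-one-causal-mutation
reading — is

$$\mathrm{AF} = \frac{O_\text{nonsynonymous} -
\lambda E_\text{nonsynonymous}}{N_\text{probands}},$$

and term-vs-preterm contrasts use z-tests
$z = (\mathrm{AF}_1 - \mathrm{AF}_2)/\sqrt{\mathrm{SE}_1^2 +
\mathrm{SE}_2^2}$ with a nine-test ledger (3 proband groups x 3 gene
sets).

Two points the methodology leaves open are resolved as follows.

* **AF uncertainty.** No variance formula is published for the
  attributable fraction. The package treats the observed count as Poisson
  with the calibrated expectation held fixed, giving
  $\mathrm{SE}(\mathrm{AF}) = \sqrt{O}/N$ and a normal 95% interval; at
  $N \approx 12{,}000$ and realistic burdens this yields interval
  half-widths of one to two percentage points, the right order of
  magnitude for such cohorts. A nonparametric bootstrap over probands
  (`attributable_fraction_boot()`) is provided as a cross-check; the two
  agree closely on simulated data (asserted in tests).
* **Where λ enters.** Whether the published Poisson tests compared O with
  raw or λ-corrected expectations is ambiguous, so both are implemented
  (`apply_lambda`, default `TRUE`, tests O against λE). The two behave
  differently under a *true* null: the raw comparison is an exact Poisson
  test and, with Bonferroni, carries a finite-sample family-wise error
  guarantee; the λ-corrected comparison inherits the sampling noise of
  λ, inflating the effective tail standard deviation by
  $\sqrt{1 + E_\text{stratum}/E_\text{synonymous}}$ and losing exactness
  precisely in the largest strata. The λ-corrected form is the right
  default for real data, where the mutational model is never exactly
  right and miscalibration dwarfs λ noise; the type-I calibration
  property, however, is a property of the exact test, and the package's
  calibration test exercises the battery in that form.

The formula is linear in (O, E) for a fixed stratum, so over any disjoint
partition of the exome the observed counts, expectations and attributable
fractions add exactly (asserted to 1e-12); exome AF always equals
DDG2P AF plus non-DDG2P AF.

# Diagnostic enrichment

Among diagnosed probands with single-gene diagnoses,
`per_gene_prematurity_association()` fits logistic regressions of binary
prematurity on the per-gene diagnosis indicator. No covariates enter by
default (an optional cohort indicator is exposed); a sensitivity rerun
restricts to clinically confirmed pathogenic/likely-pathogenic diagnoses.
Genes are testable when they carry at least 30 diagnostic variants
(`select_testable_genes()`): Monte-Carlo power analysis
(`power_to_detect()`) shows that at that count, a baseline preterm
fraction of 0.13 and the 44-gene Bonferroni level, odds ratios of six or
higher are detected with more than 80% power. The power simulation uses
the closed-form 2x2 Wald statistic, which is identical to the
logistic-regression Wald test for a single binary predictor (verified
against `glm` in the tests); empty cells fall back to Fisher's exact test
and are flagged.

`gene_set_fisher()` tests, per gene set, whether the proportion of
diagnosed probands with a diagnosis in the set differs across gestational
age groups using an exact k-by-2 Fisher test, followed by post hoc 2x2
exact tests of each preterm group against term with conditional-MLE odds
ratios. Because very and extremely preterm probands are scarce, the
grouping pools them (term / moderately / very-or-extremely preterm). The
ledger counts the overall test plus the pairwise contrasts per set — with
four sets and two pooled preterm groups that is (1 + 2) x 4 = 12 here; the
canonical four-tests-per-set ledger (0.05/16, i.e. 3.13e-3) corresponds to
an overall test plus three pairwise contrasts.

# Genetic scores

**Polygenic scores.** `compute_pgs()` forms the weighted sum of
effect-allele dosages over the variants shared between a dosage matrix and
a scoring file. Matching is by variant ID plus exact allele pair: a
swapped effect/other pair flips the dosage to $2 - d$; any other pair is
dropped with a warning — no strand flipping is attempted because scoring
pipelines harmonise strands upstream, and silent flipping of palindromic
SNPs is a classic error source. Missing dosages impute to twice the
effect-allele frequency of the non-missing carriers. Scores standardise to
mean 0, SD 1 within cohort so downstream coefficients read per SD.

**Rare variant burden score.** `compute_rvbs()` counts, per proband,
variants passing all of: autosomal, heterozygous, inherited;
high-confidence protein-truncating *or* missense-like (missense,
stop/start lost, inframe indel, low-confidence loss-of-function) with
MPC >= 2; gene pLI > 0.9; MAF < 1e-5 in every gnomAD super-population;
cohort MAF < 1e-4. The consequence mapping is the constant
`MISSENSE_LIKE_CONSEQUENCES` in the source; the cascade is monotone —
relaxing any single threshold never lowers a score (asserted).

**Score-on-gestation regressions.** Gestational duration is non-normal, so
`gd_score_regression()` applies the rank-based inverse normal transform
first (`rint()`): $\Phi^{-1}((r - 3/8)/(n + 1/4))$ with average ranks for
ties — the Blom offset, chosen as the conventional default since the
offset is not specified by the methodology and alternatives differ
negligibly at these sample sizes. Models adjust for sex and the first 20
genetic principal components (PCs are input columns; their computation is
upstream). The interaction form adds diagnostic status and a
score-by-diagnosis term.

**Trio decomposition.** To separate direct from indirect genetic effects,
`trio_decomposition()` jointly regresses the child's phenotype on the
child's, mother's and father's standardised scores. Conditional on
parental scores, the child score varies only through Mendelian
segregation, so its coefficient is the direct-effect estimate; the
parental coefficients capture the association of non-transmitted alleles
with the child's phenotype (indirect effects or residual confounding such
as assortment or stratification). An explicit non-transmitted
parameterisation (child score plus `mother + father - child` on the raw
scale) spans the same model space — the two are linear reparameterisations
of one another — and is exposed because both appear in the literature. A
child score exactly collinear with the parents (no segregation variance)
is an error. The attenuation identity motivating the design — the marginal
child-score slope equals the direct plus parental effects — is asserted in
simulation.

# The synthetic cohort generator

All generators hang off a single `sim_config()` and draw from *named
substreams* of one master seed (`substream_seed()`), so adding or
reordering a simulator never perturbs another's draws and every simulator
is a pure function of (inputs, seed); rerun equality is asserted
byte-for-byte in the tests.

Defaults are the study conditions the generator emulates: category
frequencies of 83.9 / 13.1 / 2.2 / 0.8% (term / moderate / very /
extreme) and diagnostic yields of 42.2 / 35.8 / 31.3 / 22.5% declining
with prematurity — the composition reported for large DD
clinical-sequencing cohorts. Within a category, completed weeks are
uniform on the category's integer range (term capped at 42), the simplest
choice consistent with category-level frequencies. Demographics use
plausible field values (maternal age 30 ± 5.5 y; age at assessment
7.3 ± 6.1 y; birthweight from the synthetic LMS curve).

* **DNMs** are independent Poisson per proband, gene and class at the
  rate-table rates. Excess nonsynonymous mutations are injected into
  *diagnosed* probands only (mimicking a liability-threshold architecture
  in which diagnosed cases carry the causal burden), landing in a
  uniformly chosen gene of the configured set with class split in
  proportion to the gene's missense/PTV rates; synonymous counts are never
  touched, and the base draws precede the excess draws in the stream so a
  zero-excess run is synonymous-identical, not merely
  distribution-identical.
* **Trios** draw parental genotypes binomial(2, f), transmit one allele
  per parent with probability dosage/2, and build the phenotype as
  `beta_direct * PGS_child + beta_parental * (PGS_mother + PGS_father) +
  Gaussian noise` on standardised scores — exactly the structure the trio
  decomposition assumes, which is the point: recovery of
  (beta_direct, beta_parental) is the test.
* **Milestones** are exponential with baseline rate log(2)/median and
  log-hazard shifts per category and diagnosis, independently
  right-censored with the configured probability at a uniform fraction of
  the event time. Exponential baselines satisfy proportional hazards by
  construction.
* **Rare variants** emit the full annotation schema the burden filter
  consumes with a configurable pass fraction; each failing variant breaks
  exactly one filter, uniformly chosen, so every rejection path is
  exercised.

What the generator deliberately does *not* emulate: linkage
disequilibrium, sequence-context mutation rates, genotyping-array error,
realistic HPO annotation patterns, ascertainment/collider structure, or
informative censoring. Passing tests therefore demonstrate that the
estimators are correct and calibrated under their stated assumptions —
not that those assumptions hold in any real cohort.

# Numerical choices and problem sizes

Tolerance and tie-break decisions live next to the code they govern:
probability vectors must sum to 1 within 1e-9; the LMS skewness switch is
at |L| = 1e-8; segregation variance below 1e-12 is treated as collinear;
organ-system ties break lexicographically after the closure-size rule.
Degenerate inputs (constant outcomes, no events, empty strata, zero
synonymous expectation) raise classed errors (`premdd_config_error`,
`premdd_data_error`) or flagged rows rather than silent results.

The test and acceptance workloads use scaled-down but statistically
honest sizes, chosen so Monte-Carlo tolerances (generally four standard
errors, or binomial margins for calibration rates) are meaningful:
20,000 probands for λ calibration, 10,000 for attributable-fraction
recovery, 200 replicate cohorts of 2,000 for the family-wise error of the
burden battery, 5,000 subjects for Cox recovery, 3,000 trios for the
direct/indirect dissociation, and 500 Monte-Carlo replicates for the
per-gene power computation. A synthetic exome of 100 genes (50 for the
replicate battery) with mean synonymous rate 2.5e-3 per gene keeps
expected counts in the hundreds-to-thousands range where the real
analyses operate.

# Limitations

* The organ-system tie-break is a documented stand-in for an unpublished
  rule; counts are deterministic and reproducible but not guaranteed to
  match the original assignment on multi-system terms.
* The AF standard error conditions on λ and the expectation; it ignores λ
  sampling noise (negligible when the synonymous mass is large) and any
  model misspecification.
* Fixed-effect meta-analysis only; heterogeneity is reported upstream of
  pooling but not modelled.
* The synthetic LMS reference is for testing and examples, not clinical
  use.
* The pipeline's enrichment stage draws diagnosed genes uniformly when no
  diagnosis table is supplied — a smoke-test convenience, not a model of
  gene-specific diagnostic rates.
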