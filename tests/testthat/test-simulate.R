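test_that("simulators are pure functions of (inputs, seed)", {
  cfg <- sim_config(n_probands = 400, dnm_excess = c(ddg2p = 0.1),
                    gene_sets = list(ddg2p = sprintf("G%04d", 1:10)),
                    seed = 5)
  rates <- synthetic_gene_rates(n_genes = 30, seed = 2)
  ch1 <- simulate_cohort(cfg); ch2 <- simulate_cohort(cfg)
  expect_identical(ch1, ch2)
  expect_identical(simulate_dnms(ch1, rates, cfg),
                   simulate_dnms(ch1, rates, cfg))
  t1 <- simulate_trios(ch1, cfg)
  expect_identical(t1, simulate_trios(ch1, cfg))
  expect_identical(simulate_milestones(ch1, cfg),
                   simulate_milestones(ch1, cfg))
  expect_identical(simulate_rare_variants(ch1, 20, 3),
                   simulate_rare_variants(ch1, 20, 3))
  # substreams: a different master seed changes the draws
  cfg2 <- cfg; cfg2$seed <- 6L
  expect_false(identical(ch1, simulate_cohort(cfg2)))
})

test_that("zero probands yields an empty table with the full schema", {
  cfg <- sim_config(n_probands = 0)
  ch <- simulate_cohort(cfg)
  expect_identical(nrow(ch), 0L)
  expect_true(all(c("proband_id", "sex", "gestational_weeks",
                    "prematurity_category", "birthweight_g",
                    "maternal_age_years", "age_at_assessment_years",
                    "diagnosed", "hpo_terms", "deprivation_index")
                  %in% names(ch)))
})

test_that("category frequencies land within 3 binomial SDs of their targets", {
  p <- c(term = 0.84, moderate = 0.13, very = 0.022, extreme = 0.008)
  cfg <- sim_config(n_probands = 20000, category_probs = p, seed = 17)
  ch <- simulate_cohort(cfg)
  obs <- table(ch$prematurity_category) / nrow(ch)
  for (k in names(p)) {
    sd_k <- sqrt(p[[k]] * (1 - p[[k]]) / 20000)
    expect_lt(abs(obs[[k]] - p[[k]]), 3 * sd_k)
  }
  # weeks always consistent with the WHO rule
  expect_identical(as.character(classify_prematurity(ch$gestational_weeks)),
                   as.character(ch$prematurity_category))
  expect_true(all(ch$gestational_weeks >= 22 & ch$gestational_weeks <= 42))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(category_probs = c(0.5, 0.5, 0.1, 0.1)), "sum to 1")
  expect_error(sim_config(n_probands = -1), "non-negative")
  expect_error(sim_config(dnm_excess = c(zz = 0.1)), "gene set")
  expect_error(sim_config(trio_params = list(n_variants = 2, allele_freqs = 1.2,
                                             weights = 1, beta_direct = 0,
                                             beta_parental = 0, noise_sd = 1)),
               "allele_freqs")
})

test_that("null DNM totals match the Poisson expectation; excess spares synonymous", {
  cfg0 <- sim_config(n_probands = 4000, seed = 21)
  rates <- synthetic_gene_rates(n_genes = 40, seed = 2)
  ch <- simulate_cohort(cfg0)
  dn0 <- simulate_dnms(ch, rates, cfg0)
  expected_total <- 4000 * sum(rates$mu)
  expect_lt(abs(nrow(dn0) - expected_total), 4 * sqrt(expected_total))
  expect_error(simulate_dnms(ch, transform(rates, mu = -mu), cfg0),
               ">= 0")

  # same seed stream, excess on: synonymous rows are byte-identical
  cfg1 <- cfg0
  cfg1$gene_sets <- list(ddg2p = unique(rates$gene[rates$ddg2p]))
  cfg1$dnm_excess <- c(ddg2p = 0.2)
  dn1 <- simulate_dnms(ch, rates, cfg1)
  syn0 <- dn0[dn0$class == "synonymous", ]
  syn1 <- dn1[dn1$class == "synonymous", ]
  expect_identical(syn0, syn1)
  # extra mutations are nonsynonymous, in the configured set, diagnosed only
  extra_n <- nrow(dn1) - nrow(dn0)
  expect_gt(extra_n, 0)
  added <- dn1[(nrow(dn0) + 1):nrow(dn1), ]
  expect_true(all(added$class %in% c("missense", "ptv")))
  expect_true(all(added$gene %in% cfg1$gene_sets$ddg2p))
  diag_ids <- ch$proband_id[ch$diagnosed == 1]
  expect_true(all(added$proband_id %in% diag_ids))
})

test_that("trio simulation obeys Mendelian expectations", {
  cfg <- sim_config(n_probands = 3000, seed = 31,
                    trio_params = list(n_variants = 80, allele_freqs = 0.3,
                                       weights = 1, beta_direct = 0,
                                       beta_parental = 0, noise_sd = 1))
  ch <- simulate_cohort(cfg)
  tr <- simulate_trios(ch, cfg)
  # null: regression of phenotype on child PGS gives |beta| < 4 SE
  fit <- summary(lm(tr$phenotype ~ tr$scores$child))
  expect_lt(abs(fit$coefficients[2, 1]), 4 * fit$coefficients[2, 2])
  # random transmission: mean child raw score ~ mean parental raw score
  raw_child <- rowSums(tr$dosages$child)
  raw_parent <- (rowSums(tr$dosages$mother) + rowSums(tr$dosages$father)) / 2
  se_diff <- sd(raw_child - raw_parent) / sqrt(length(raw_child))
  expect_lt(abs(mean(raw_child) - mean(raw_parent)), 4 * se_diff)
  # dosage bookkeeping: child = transmitted = parent - nontransmitted
  expect_true(all(tr$dosages$mother - tr$nontransmitted$mother +
                    tr$dosages$father - tr$nontransmitted$father ==
                    tr$dosages$child))

  cfg0 <- cfg
  cfg0$trio_params$n_variants <- 0L
  cfg0$trio_params$allele_freqs <- numeric(0)
  cfg0$trio_params$weights <- numeric(0)
  tr0 <- simulate_trios(ch, cfg0)
  expect_true(all(tr0$scores$child == 0))
  expect_equal(sd(tr0$phenotype), 1, tolerance = 0.1) # pure noise
})

test_that("milestone times follow the configured hazards and censoring", {
  mp <- list(baseline_median_months = c(walk = 15),
             log_hr_by_category = c(moderate = 0, very = 0, extreme = 0),
             log_hr_diagnosis = log(0.5), censor_prob = 0.05)
  cfg <- sim_config(n_probands = 5000, seed = 41, milestone_params = mp)
  ch <- simulate_cohort(cfg)
  ms <- simulate_milestones(ch, cfg)
  cox <- cox_milestone_model(ms$ms_walk_months, ms$ms_walk_event,
                             data.frame(diagnosed = ms$diagnosed))
  expect_gt(cox$hr[cox$term == "diagnosed"], 0.4)
  expect_lt(cox$hr[cox$term == "diagnosed"], 0.6)

  # identical distributions across categories when all log-HRs are zero:
  # per-category Kaplan-Meier medians agree within resampling error
  cfg_null <- cfg
  cfg_null$milestone_params$log_hr_diagnosis <- 0
  ms0 <- simulate_milestones(ch, cfg_null)
  for (cc in levels(ms0$prematurity_category)) {
    i <- which(ms0$prematurity_category == cc)
    f <- survival::survfit(survival::Surv(ms0$ms_walk_months[i],
                                          ms0$ms_walk_event[i]) ~ 1)
    med <- unname(summary(f)$table["median"])
    # asymptotic SE of an exponential sample median: (m / log 2) / sqrt(n)
    expect_lt(abs(med - 15), 4 * (15 / log(2)) / sqrt(length(i)))
  }

  # full censoring degenerates downstream
  cfg_cens <- cfg
  cfg_cens$milestone_params$censor_prob <- 1
  msc <- simulate_milestones(ch, cfg_cens)
  expect_true(all(msc$ms_walk_event == 0))
  expect_error(km_logrank(msc$ms_walk_months, msc$ms_walk_event,
                          msc$prematurity_category), "no events")
  expect_error(sim_config(milestone_params = list(
    baseline_median_months = c(walk = -1), log_hr_by_category = c(0, 0, 0),
    log_hr_diagnosis = 0, censor_prob = 0.1)), "> 0")
})

test_that("rare-variant generator controls the filter pass fraction", {
  cfg <- sim_config(n_probands = 600, seed = 51)
  ch <- simulate_cohort(cfg)
  v0 <- simulate_rare_variants(ch, 20, seed = 7, n_variants_per_proband = 4,
                               pass_fraction = 0)
  expect_true(all(compute_rvbs(v0, ch$proband_id) == 0))

  f <- 0.4; k <- 4
  v <- simulate_rare_variants(ch, 20, seed = 7, n_variants_per_proband = k,
                              pass_fraction = f)
  scores <- compute_rvbs(v, ch$proband_id)
  se <- sqrt(f * (1 - f) * k / length(scores))
  expect_lt(abs(mean(scores) - f * k), 4 * se)
  # every non-passing variant fails at least one named filter
  expect_identical(sum(rvbs_pass(v)), sum(scores))
})
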