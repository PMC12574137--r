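test_that("expected counts are rate sums scaled by probands", {
  rates <- data.frame(gene = "g1", class = "missense", mu = 1e-5)
  expect_equal(expected_dnm_counts(rates, 1000, "g1", "missense"), 0.01)
  expect_equal(expected_dnm_counts(rates, 1000, character(0)), 0)
  expect_error(expected_dnm_counts(rates, 10, "g2"), "absent")
  expect_error(expected_dnm_counts(transform(rates, mu = -1), 10, "g1"),
               ">= 0")

  # 50-gene random table equals the brute-force double loop
  set.seed(15)
  rt <- expand.grid(gene = sprintf("g%02d", 1:50),
                    class = c("synonymous", "missense", "ptv"),
                    stringsAsFactors = FALSE)
  rt$mu <- runif(nrow(rt), 0, 1e-4)
  gset <- sample(unique(rt$gene), 20)
  oracle <- 0
  for (g in gset) for (cc in c("missense", "ptv"))
    oracle <- oracle + 7500 * rt$mu[rt$gene == g & rt$class == cc]
  expect_equal(expected_dnm_counts(rt, 7500, gset, c("missense", "ptv")),
               oracle, tolerance = 1e-12)
})

test_that("the synonymous calibration factor is O/E over all probands", {
  rates <- data.frame(gene = "g1", class = "synonymous", mu = 0.01)
  dnms <- data.frame(proband_id = sprintf("P%d", 1:120), gene = "g1",
                     class = "synonymous")
  # E = 10000 * 0.01 = 100, O = 120
  expect_equal(synonymous_correction_factor(dnms, rates, 10000), 1.2)
  expect_equal(synonymous_correction_factor(dnms, rates, 12000), 1)
  expect_warning(
    l0 <- synonymous_correction_factor(dnms[0, ], rates, 100),
    "degenerate")
  expect_equal(l0, 0)
  expect_error(synonymous_correction_factor(
    dnms, data.frame(gene = "g1", class = "synonymous", mu = 0), 100),
    "zero")
})

test_that("the exact Poisson excess test matches pmf summation", {
  expect_equal(poisson_excess_test(0, 5), 1)
  # P(X >= 5 | mean 1) = 1 - sum_{k<=4} e^-1 / k!
  oracle <- 1 - sum(exp(-1) / factorial(0:4))
  expect_equal(poisson_excess_test(5, 1), oracle, tolerance = 1e-12)
  expect_equal(round(poisson_excess_test(5, 1), 6), 0.003660)
  # Poisson median property: p(O = mean) near one half for large mean
  expect_lt(abs(poisson_excess_test(1000, 1000) - 0.5), 0.02)
  expect_error(poisson_excess_test(-1, 5), ">= 0")
  expect_error(poisson_excess_test(1, 0), "> 0")
})

test_that("Poisson excess p-values are uniform-conservative under the null", {
  set.seed(16)
  mean_ <- 40
  ps <- vapply(rpois(2000, mean_), poisson_excess_test, numeric(1),
               expected_corrected = mean_)
  # P(p <= a) <= a for exact one-sided tests, discreteness aside
  for (a in c(0.01, 0.05, 0.1, 0.25)) expect_lte(mean(ps <= a), a + 0.02)
  expect_lt(suppressWarnings(ks.test(ps, "punif"))$statistic, 0.08)
})

test_that("the attributable fraction follows its defining formula", {
  af <- attributable_fraction(100, 60, 1, 200)
  expect_equal(af$af, 0.20)
  expect_equal(af$se, sqrt(100) / 200)
  expect_equal(af$ci, 0.20 + c(-1, 1) * qnorm(0.975) * sqrt(100) / 200)
  expect_equal(attributable_fraction(50, 50, 1, 100)$af, 0)  # O = lambda E
  expect_error(attributable_fraction(10, 5, 1, 0), "> 0")
})

test_that("AF z-test comparisons match the normal CDF oracle", {
  same <- compare_attributable_fractions(list(af = 0.2, se = 0.01),
                                         list(af = 0.2, se = 0.02))
  expect_equal(same$z, 0); expect_equal(same$p, 1)

  cmp <- compare_attributable_fractions(list(af = 0.25, se = 0.01),
                                        list(af = 0.20, se = 0.015))
  z_oracle <- 0.05 / sqrt(0.01^2 + 0.015^2)
  expect_equal(cmp$z, z_oracle, tolerance = 1e-10)
  expect_equal(round(cmp$z, 4), 2.7735)
  expect_equal(cmp$p, 2 * pnorm(-z_oracle), tolerance = 1e-12)
  expect_equal(round(cmp$p, 5), 0.00555)
  expect_error(compare_attributable_fractions(list(af = 1, se = NA),
                                              list(af = 1, se = 1)), "finite")

  # type-I calibration: identical Poisson groups, 200 replicates
  set.seed(17)
  n1 <- 4000; n2 <- 1000; mu <- 0.6
  hits <- vapply(1:200, function(i) {
    o1 <- rpois(1, n1 * mu); o2 <- rpois(1, n2 * mu)
    r1 <- list(af = (o1 - n1 * mu) / n1, se = sqrt(o1) / n1)
    r2 <- list(af = (o2 - n2 * mu) / n2, se = sqrt(o2) / n2)
    abs(compare_attributable_fractions(r1, r2)$z) > qnorm(0.975)
  }, logical(1))
  expect_lte(mean(hits), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("the stratified battery is additive over disjoint gene sets", {
  cfg <- sim_config(n_probands = 3000, seed = 91)
  ch <- simulate_cohort(cfg)
  rates <- synthetic_gene_rates(n_genes = 60, seed = 4)
  dnms <- simulate_dnms(ch, rates, cfg)
  b <- run_dnm_analysis(ch, dnms, rates)
  s <- b$strata
  for (g in c("term", "preterm")) for (pg in c("all", "diagnosed", "undiagnosed")) {
    sel <- s$gestation == g & s$proband_group == pg
    ex <- s[sel & s$gene_set == "exome", ]
    dd <- s[sel & s$gene_set == "ddg2p", ]
    nd <- s[sel & s$gene_set == "non_ddg2p", ]
    expect_identical(ex$observed, dd$observed + nd$observed)
    expect_equal(ex$expected, dd$expected + nd$expected, tolerance = 1e-12)
    # AF additivity: common N and lambda make the formula linear in (O, E)
    expect_equal(ex$af, dd$af + nd$af, tolerance = 1e-12)
  }
  expect_identical(b$ledgers$poisson$n_tests, 18L)
  expect_identical(b$ledgers$af_comparison$n_tests, 9L)
  expect_error(run_dnm_analysis(ch, transform(dnms, proband_id = "nope"),
                                rates), "not in cohort")
})

test_that("injected DDG2P excess in diagnosed term probands is recovered", {
  rates <- synthetic_gene_rates(n_genes = 60, seed = 4)
  ddg2p <- unique(rates$gene[rates$ddg2p])
  excess_rate <- 0.3
  cfg <- sim_config(n_probands = 8000, seed = 95,
                    dnm_excess = c(ddg2p = excess_rate),
                    gene_sets = list(ddg2p = ddg2p))
  ch <- simulate_cohort(cfg)
  # confine the injected excess to term probands: undiagnose preterm cases
  ch$diagnosed[ch$prematurity_category != "term"] <- 0
  dnms <- simulate_dnms(ch, rates, cfg)
  b <- run_dnm_analysis(ch, dnms, rates)
  s <- b$strata
  term <- s[s$gestation == "term" & s$proband_group == "all" &
              s$gene_set == "ddg2p", ]
  pre <- s[s$gestation == "preterm" & s$proband_group == "all" &
             s$gene_set == "ddg2p", ]
  injected_diff <- excess_rate * mean(ch$diagnosed[ch$prematurity_category == "term"])
  pooled_se <- sqrt(term$af_se^2 + pre$af_se^2)
  expect_lt(abs((term$af - pre$af) - injected_diff), 4 * pooled_se)
  cmp <- b$comparisons[b$comparisons$proband_group == "all" &
                         b$comparisons$gene_set == "ddg2p", ]
  expect_lt(cmp$p, 0.05 / 9)
})

test_that("bootstrap AF uncertainty agrees with the Poisson-count SE", {
  cfg <- sim_config(n_probands = 4000, seed = 97)
  ch <- simulate_cohort(cfg)
  rates <- synthetic_gene_rates(n_genes = 40, seed = 4)
  dnms <- simulate_dnms(ch, rates, cfg)
  lam <- synonymous_correction_factor(dnms, rates, nrow(ch))
  boot <- attributable_fraction_boot(dnms, ch$proband_id, rates,
                                     unique(rates$gene), lam,
                                     n_boot = 300, seed = 5)
  o <- sum(dnms$class %in% c("missense", "ptv"))
  analytic <- attributable_fraction(
    o, expected_dnm_counts(rates, nrow(ch)), lam, nrow(ch))
  expect_equal(boot$af, analytic$af, tolerance = 1e-12)
  expect_lt(abs(boot$se - analytic$se) / analytic$se, 0.35)
})
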