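test_that("polygenic scores are weighted dosage sums with allele matching", {
  w <- data.frame(variant_id = "v1", effect_allele = "A", other_allele = "G",
                  weight = 0.5)
  d <- matrix(2, 1, 1, dimnames = list("P1", "v1"))
  expect_equal(compute_pgs(d, w)$raw_score, 1.0)

  w0 <- transform(w, weight = 0)
  expect_equal(compute_pgs(d, w0)$raw_score, 0)

  # 100-variant random table equals the brute-force per-individual loop
  set.seed(27)
  v <- sprintf("v%03d", 1:100)
  ww <- data.frame(variant_id = v, effect_allele = "A", other_allele = "G",
                   weight = rnorm(100))
  dd <- matrix(rbinom(30 * 100, 2, 0.4), 30, 100,
               dimnames = list(sprintf("P%02d", 1:30), v))
  got <- compute_pgs(dd, ww)
  oracle <- vapply(1:30, function(i) sum(dd[i, ] * ww$weight), numeric(1))
  expect_equal(got$raw_score, oracle, tolerance = 1e-12)
  expect_equal(mean(got$score), 0, tolerance = 1e-12)
  expect_equal(sd(got$score), 1, tolerance = 1e-12)

  # swapped allele pair flips dosage; mismatched pair dropped with warning
  da <- data.frame(variant_id = c("v001", "v002", "v003"),
                   effect_allele = c("A", "G", "T"),
                   other_allele = c("G", "A", "C"))
  w3 <- data.frame(variant_id = c("v001", "v002", "v003"),
                   effect_allele = "A", other_allele = "G",
                   weight = c(1, 1, 1))
  d3 <- matrix(c(2, 2, 2), 1, 3, dimnames = list("P1", da$variant_id))
  expect_warning(res3 <- compute_pgs(d3, w3, dosage_alleles = da),
                 "mismatch")
  expect_equal(res3$raw_score, 2 + (2 - 2))  # v1 direct + v2 flipped, v3 out
  expect_equal(attr(res3, "n_variants"), 2L)

  # missing dosages impute to twice the effect-allele frequency
  dm <- matrix(c(2, 0, NA), 3, 1, dimnames = list(NULL, "v1"))
  rm_ <- compute_pgs(dm, w)
  expect_equal(rm_$raw_score[3], 0.5 * mean(c(2, 0)))
  expect_error(compute_pgs(matrix(1, 1, 1, dimnames = list(NULL, "zz")), w),
               "no overlapping")
})

test_that("the burden-score cascade applies every filter boundary", {
  expect_identical(unname(compute_rvbs(rv_row())), 1L)
  # MPC 1.9 missense otherwise passing: excluded
  expect_identical(unname(compute_rvbs(
    rv_row(consequence = "missense", loftee_confidence = NA, mpc = 1.9))), 0L)
  expect_identical(unname(compute_rvbs(
    rv_row(consequence = "missense", loftee_confidence = NA, mpc = 2.0))), 1L)
  # each remaining filter boundary
  expect_identical(unname(compute_rvbs(rv_row(cohort_maf = 2e-4))), 0L)
  expect_identical(unname(compute_rvbs(rv_row(gnomad_max_maf = 2e-5))), 0L)
  expect_identical(unname(compute_rvbs(rv_row(pli = 0.9))), 0L)
  expect_identical(unname(compute_rvbs(rv_row(inherited = FALSE))), 0L)
  expect_identical(unname(compute_rvbs(rv_row(zygosity = "hom"))), 0L)
  expect_identical(unname(compute_rvbs(rv_row(autosomal = FALSE))), 0L)
  expect_identical(unname(compute_rvbs(rv_row(loftee_confidence = "LC"))), 0L)
  # LC loss-of-function is missense-like: MPC >= 2 rescues it
  expect_identical(unname(compute_rvbs(
    rv_row(loftee_confidence = "LC", mpc = 2.5))), 1L)
  expect_error(compute_rvbs(rv_row()[-3]), "missing columns")

  # full toy table matches manual filter application
  set.seed(28)
  cfg <- sim_config(n_probands = 150, seed = 4)
  ch <- simulate_cohort(cfg)
  v <- simulate_rare_variants(ch, 10, seed = 6, pass_fraction = 0.5)
  manual <- with(v, autosomal & zygosity == "het" & inherited &
    ((consequence == "ptv" & !is.na(loftee_confidence) & loftee_confidence == "HC") |
     ((consequence %in% c("missense", "stop_lost", "start_lost",
                          "inframe_insertion", "inframe_deletion") |
       (consequence == "ptv" & !is.na(loftee_confidence) & loftee_confidence == "LC")) &
      !is.na(mpc) & mpc >= 2)) &
    pli > 0.9 & gnomad_max_maf < 1e-5 & cohort_maf < 1e-4)
  expect_identical(rvbs_pass(v), manual)

  # monotonicity: relaxing any single annotation never lowers a score
  base_scores <- compute_rvbs(v, ch$proband_id)
  relaxed <- v; relaxed$pli <- 1
  expect_true(all(compute_rvbs(relaxed, ch$proband_id) >= base_scores))
  relaxed2 <- v; relaxed2$cohort_maf <- 0
  expect_true(all(compute_rvbs(relaxed2, ch$proband_id) >= base_scores))
})

test_that("the rank inverse-normal transform is the Blom transform", {
  expect_equal(rint(c(5, 1, 9))[1], 0)  # middle rank of n = 3
  expect_equal(round(rint(c(5, 1, 9))[2], 4), -0.8694)
  expect_equal(rint(c(5, 1, 9))[2], qnorm((1 - 3 / 8) / (3 + 1 / 4)))
  x <- c(2.3, -1, 0.5, 7, 4)
  expect_equal(rint(x), -rint(-x))               # rank-reversal symmetry
  expect_lt(abs(mean(rint(x))), 1e-8)
  expect_identical(order(rint(x)), order(x))     # rank-preserving
  xm <- c(1, NA, 3, 2)
  expect_true(is.na(rint(xm)[2]))                # missing propagated
  expect_error(rint(c(1, 1, 1)), "equal")
  expect_error(rint(1), ">= 2")
})

test_that("score regressions are null-calibrated and recover injected betas", {
  set.seed(29)
  n <- 10000
  pcs <- matrix(rnorm(n * 20), n, 20,
                dimnames = list(NULL, paste0("PC", 1:20)))
  covs <- data.frame(sex = sample(c("F", "M"), n, TRUE), pcs)
  score <- rnorm(n)
  out <- 0.05 * score + rnorm(n)  # standardised beta ~ 0.05 per SD of score
  res <- gd_score_regression(out, score, covs)
  b <- res[res$term == "score", ]
  expect_gt(b$estimate, 0.01); expect_lt(b$estimate, 0.09)

  # null score
  res0 <- gd_score_regression(rnorm(n), score, covs)
  b0 <- res0[res0$term == "score", ]
  expect_lt(abs(b0$estimate), 4 * b0$se)

  # interaction attenuation recovered with the right sign
  diag_ <- rbinom(n, 1, 0.4)
  hits <- 0
  for (r in 1:50) {
    set.seed(600 + r)
    sc <- rnorm(4000); dg <- rbinom(4000, 1, 0.4)
    y <- 0.05 * sc - 0.05 * sc * dg + rnorm(4000)
    ri <- gd_score_regression(y, sc, covs[1:4000, ], diagnosed = dg,
                              interaction = TRUE)
    it <- ri[ri$term == "score:diagnosed", ]
    if (it$estimate < 0 && abs(it$estimate - (-0.05)) < 4 * it$se)
      hits <- hits + 1
  }
  expect_gte(hits / 50, 0.9)

  expect_error(gd_score_regression(out, score, covs[, 1:10, drop = FALSE]),
               "PC columns")
  covs_bad <- covs; covs_bad$PC20 <- covs_bad$PC19
  expect_error(gd_score_regression(out, score, covs_bad), "rank-deficient")
})

test_that("trio decomposition separates direct from parental components", {
  mk <- function(bd, bp, seed) {
    cfg <- sim_config(n_probands = 3000, seed = seed,
                      trio_params = list(n_variants = 80, allele_freqs = 0.3,
                                         weights = 1, beta_direct = bd,
                                         beta_parental = bp, noise_sd = 1))
    simulate_trios(simulate_cohort(cfg), cfg)
  }
  # pure direct effect
  trd <- mk(0.1, 0, 101)
  rd <- trio_decomposition(trd$scores$child, trd$scores$mother,
                           trd$scores$father, trd$phenotype)
  bchild <- rd[rd$term == "child", ]
  expect_lt(abs(bchild$estimate - 0.1), 4 * bchild$se)
  for (p in c("mother", "father")) {
    bp_ <- rd[rd$term == p, ]
    expect_lt(abs(bp_$estimate), 4 * bp_$se)
  }
  # pure parental effect
  trp <- mk(0, 0.1, 102)
  rp <- trio_decomposition(trp$scores$child, trp$scores$mother,
                           trp$scores$father, trp$phenotype)
  expect_lt(abs(rp$estimate[rp$term == "child"]),
            4 * rp$se[rp$term == "child"])
  for (p in c("mother", "father")) {
    bp_ <- rp[rp$term == p, ]
    expect_lt(abs(bp_$estimate - 0.1), 4 * bp_$se)
    expect_gt(bp_$estimate, 0)
  }
  # attenuation identity: marginal child slope ~ beta_direct + beta_parental
  trb <- mk(0.06, 0.04, 103)
  marg <- summary(lm(trb$phenotype ~ trb$scores$child))$coefficients
  expect_lt(abs(marg[2, 1] - 0.1), 4 * marg[2, 2])

  # no segregation variance
  expect_error(trio_decomposition(trd$scores$mother + trd$scores$father,
                                  trd$scores$mother, trd$scores$father,
                                  trd$phenotype), "segregation")

  # the non-transmitted parameterisation spans the same fit
  rn <- trio_decomposition(trd$scores$child, trd$scores$mother,
                           trd$scores$father, trd$phenotype,
                           parameterisation = "nontransmitted")
  expect_setequal(rn$term[-1], c("child", "nontransmitted"))
})
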