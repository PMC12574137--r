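#' Simulation configuration for synthetic developmental-disorder cohorts
#'
#' Bundles every tunable of the synthetic generators. Defaults emulate the
#' composition of large clinical-sequencing DD cohorts: roughly 84% term,
#' 13% moderately, 2.2% very and 0.8% extremely preterm probands, with
#' diagnostic yield declining with the degree of prematurity (42%, 36%, 31%,
#' 23%).
#'
#' @param n_probands Number of probands to simulate.
#' @param category_probs Probabilities of term/moderate/very/extreme (sum 1).
#' @param diag_prob_by_category Probability of a monogenic diagnosis within
#'   each category, same order.
#' @param dnm_excess Named numeric vector: extra nonsynonymous de novo
#'   mutations per *diagnosed* proband, per named gene set (Poisson rate).
#' @param gene_sets Named list of gene-ID vectors referenced by `dnm_excess`.
#' @param trio_params List: `n_variants`, `allele_freqs` (recycled to
#'   `n_variants`, each in (0,1)), `weights`, `beta_direct`, `beta_parental`,
#'   `noise_sd`.
#' @param milestone_params List: `baseline_median_months` (named per
#'   milestone), `log_hr_by_category` (named `moderate`, `very`, `extreme`;
#'   term is the reference), `log_hr_diagnosis`, `censor_prob`.
#' @param seed Master integer seed; each simulator draws from its own named
#'   substream (see [substream_seed]).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_probands = 10000,
                       category_probs = c(term = 0.839, moderate = 0.131,
                                          very = 0.022, extreme = 0.008),
                       diag_prob_by_category = c(term = 0.422, moderate = 0.358,
                                                 very = 0.313, extreme = 0.225),
                       dnm_excess = numeric(0),
                       gene_sets = list(),
                       trio_params = list(n_variants = 100,
                                          allele_freqs = 0.3,
                                          weights = 1,
                                          beta_direct = 0,
                                          beta_parental = 0,
                                          noise_sd = 1),
                       milestone_params = list(
                         baseline_median_months = c(smile = 2, sit = 9,
                                                    walk = 15, words = 13),
                         log_hr_by_category = c(moderate = 0, very = 0,
                                                extreme = 0),
                         log_hr_diagnosis = 0,
                         censor_prob = 0.1),
                       seed = 1L) {
  if (!is.numeric(n_probands) || length(n_probands) != 1 || n_probands < 0 ||
      n_probands != floor(n_probands))
    stop_config("n_probands must be a non-negative integer")
  check_prob_vector(category_probs, "category_probs")
  if (length(category_probs) != 4 || length(diag_prob_by_category) != 4)
    stop_config("category_probs and diag_prob_by_category must have length 4")
  if (any(diag_prob_by_category < 0 | diag_prob_by_category > 1))
    stop_config("diag_prob_by_category must lie in [0, 1]")
  if (length(dnm_excess)) {
    if (any(dnm_excess < 0)) stop_config("dnm_excess rates must be >= 0")
    missing_sets <- setdiff(names(dnm_excess), names(gene_sets))
    if (length(missing_sets))
      stop_config("dnm_excess names without a gene set: ",
                  paste(missing_sets, collapse = ", "))
  }
  tp <- trio_params
  tp$allele_freqs <- rep_len(tp$allele_freqs, tp$n_variants)
  tp$weights <- rep_len(tp$weights, tp$n_variants)
  if (tp$n_variants > 0 &&
      (any(tp$allele_freqs <= 0) || any(tp$allele_freqs >= 1)))
    stop_config("allele_freqs must lie strictly in (0, 1)")
  if (tp$noise_sd < 0) stop_config("noise_sd must be >= 0")
  mp <- milestone_params
  if (any(mp$baseline_median_months <= 0))
    stop_config("baseline_median_months must be > 0")
  if (mp$censor_prob < 0 || mp$censor_prob > 1)
    stop_config("censor_prob must lie in [0, 1]")
  if (!is.numeric(seed) || length(seed) != 1)
    stop_config("seed must be a single integer")
  names(category_probs) <- names(diag_prob_by_category) <- PREMATURITY_LEVELS
  structure(list(n_probands = as.integer(n_probands),
                 category_probs = category_probs,
                 diag_prob_by_category = diag_prob_by_category,
                 dnm_excess = dnm_excess, gene_sets = gene_sets,
                 trio_params = tp, milestone_params = mp,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Synthetic LMS birthweight reference over weeks 22-44; the median follows a
# Hadlock-style log-quadratic fetal weight curve, constant skewness and CV.
lms_synthetic_reference <- function(weeks = 22:44) {
  grid <- expand.grid(sex = c("F", "M"), gestational_weeks = weeks,
                      stringsAsFactors = FALSE)
  m <- exp(0.578 + 0.332 * grid$gestational_weeks -
             0.00354 * grid$gestational_weeks^2)
  m <- m * ifelse(grid$sex == "M", 1.04, 0.96)
  as_lms_reference(data.frame(grid, L = 1, M = m, S = 0.11))
}

#' Simulate a synthetic developmental-disorder cohort
#'
#' Draws gestational age group per the configured frequencies, completed
#' weeks uniformly on the category's integer range (term capped at 42),
#' a Bernoulli monogenic diagnosis with category-specific probability, and
#' plausible demographics (sex, maternal age, age at assessment, birthweight
#' from a synthetic LMS reference, deprivation index).
#'
#' @param config A [sim_config].
#' @return A data frame (`cohort_table`), one row per proband.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_probands
  empty <- data.frame(proband_id = character(0), cohort_label = character(0),
                      sex = character(0), gestational_weeks = integer(0),
                      prematurity_category =
                        factor(character(0), levels = PREMATURITY_LEVELS),
                      birthweight_g = numeric(0),
                      maternal_age_years = numeric(0),
                      age_at_assessment_years = numeric(0),
                      diagnosed = integer(0), hpo_terms = character(0),
                      deprivation_index = numeric(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  with_substream(config$seed, "cohort", {
    cat_ <- sample(PREMATURITY_LEVELS, n, replace = TRUE,
                   prob = config$category_probs)
    ranges <- vapply(cat_, category_week_range, integer(2))
    weeks <- ranges[1, ] + floor(runif(n) * (ranges[2, ] - ranges[1, ] + 1))
    weeks <- pmin(as.integer(weeks), ranges[2, ])
    diagnosed <- rbinom(n, 1, config$diag_prob_by_category[cat_])
    sex <- sample(c("F", "M"), n, replace = TRUE)
    ref <- lms_synthetic_reference()
    idx <- match(paste(sex, weeks), paste(ref$sex, ref$gestational_weeks))
    bw <- ref$M[idx] * (1 + ref$S[idx] * rnorm(n))
    bw <- pmax(bw, 150)
    data.frame(proband_id = sprintf("P%06d", seq_len(n)),
               cohort_label = "SYNTH",
               sex = sex,
               gestational_weeks = as.integer(weeks),
               prematurity_category = factor(cat_, levels = PREMATURITY_LEVELS),
               birthweight_g = round(bw),
               maternal_age_years = round(pmax(rnorm(n, 30, 5.5), 15), 1),
               age_at_assessment_years = round(pmax(rnorm(n, 7.3, 6.1), 0.2), 1),
               diagnosed = diagnosed,
               hpo_terms = "",
               deprivation_index = rnorm(n),
               stringsAsFactors = FALSE)
  })
}

#' Simulate de novo mutations under a per-gene Poisson null
#'
#' Per proband, gene and consequence class, counts are independent Poisson
#' with the gene/class rate from `rates`. Diagnosed probands additionally
#' receive excess nonsynonymous mutations in each gene set named in
#' `config$dnm_excess`, at the configured per-proband rate; each excess
#' mutation lands in a uniformly chosen gene of the set, with class missense
#' or protein-truncating chosen in proportion to the gene's nonsynonymous
#' rates. Synonymous counts never receive excess.
#'
#' @param cohort A cohort table from [simulate_cohort].
#' @param rates A gene rate table (see [read_gene_rates]): columns `gene`,
#'   `class` in `synonymous`/`missense`/`ptv`, `mu`.
#' @param config A [sim_config].
#' @return Data frame with one row per mutation: `proband_id`, `gene`,
#'   `class`.
#' @export
simulate_dnms <- function(cohort, rates, config) {
  rates <- validate_gene_rates(rates)
  n <- nrow(cohort)
  out0 <- data.frame(proband_id = character(0), gene = character(0),
                     class = character(0), stringsAsFactors = FALSE)
  if (n == 0L) return(out0)
  with_substream(config$seed, "dnm", {
    k <- nrow(rates)
    # base null draws: proband-major so the stream is stable in n
    counts <- rpois(n * k, rep(rates$mu, each = n))
    nz <- which(counts > 0L)
    base <- if (length(nz)) {
      pi <- ((nz - 1L) %% n) + 1L
      ri <- ((nz - 1L) %/% n) + 1L
      data.frame(proband_id = rep(cohort$proband_id[pi], counts[nz]),
                 gene = rep(rates$gene[ri], counts[nz]),
                 class = rep(rates$class[ri], counts[nz]),
                 stringsAsFactors = FALSE)
    } else out0
    extra <- out0
    if (length(config$dnm_excess)) {
      diag_ids <- cohort$proband_id[cohort$diagnosed == 1]
      for (set_name in names(config$dnm_excess)) {
        rate <- config$dnm_excess[[set_name]]
        genes <- intersect(config$gene_sets[[set_name]], rates$gene)
        if (rate <= 0 || !length(genes) || !length(diag_ids)) next
        m <- rpois(length(diag_ids), rate)
        tot <- sum(m)
        if (tot == 0) next
        g <- sample(genes, tot, replace = TRUE)
        # class in proportion to the gene's nonsynonymous rates
        mis <- rates$mu[match(paste(g, "missense"), paste(rates$gene, rates$class))]
        ptv <- rates$mu[match(paste(g, "ptv"), paste(rates$gene, rates$class))]
        mis[is.na(mis)] <- 0; ptv[is.na(ptv)] <- 0
        pm <- ifelse(mis + ptv > 0, mis / (mis + ptv), 0.5)
        cls <- ifelse(runif(tot) < pm, "missense", "ptv")
        extra <- rbind(extra, data.frame(
          proband_id = rep(diag_ids, m), gene = g, class = cls,
          stringsAsFactors = FALSE))
      }
    }
    rbind(base, extra)
  })
}

#' Simulate genotyped parent-offspring trios with a polygenic phenotype
#'
#' Parental genotypes are binomial(2, allele frequency); each parent
#' transmits one allele per variant with probability dosage/2, and the child
#' dosage is the sum of the two transmitted alleles (Mendelian transmission).
#' Raw polygenic scores are the weighted dosage sums; after standardisation
#' the phenotype is
#' `beta_direct * PGS_child + beta_parental * (PGS_mother + PGS_father) +
#' noise`.
#'
#' @param cohort A cohort table; one trio per proband row.
#' @param config A [sim_config] whose `trio_params` are used.
#' @return List with `dosages` (list of child/mother/father matrices),
#'   `nontransmitted` (mother/father non-transmitted dosage matrices),
#'   `scores` (data frame of standardised child/mother/father PGS) and
#'   `phenotype` (numeric vector).
#' @export
simulate_trios <- function(cohort, config) {
  tp <- config$trio_params
  n <- nrow(cohort)
  v <- tp$n_variants
  with_substream(config$seed, "trio", {
    if (v == 0L) {
      zero <- matrix(0, n, 0)
      sc <- data.frame(child = rep(0, n), mother = rep(0, n),
                       father = rep(0, n))
      return(list(dosages = list(child = zero, mother = zero, father = zero),
                  nontransmitted = list(mother = zero, father = zero),
                  scores = sc,
                  phenotype = rnorm(n, 0, tp$noise_sd)))
    }
    f <- matrix(tp$allele_freqs, n, v, byrow = TRUE)
    gm <- matrix(rbinom(n * v, 2, f), n, v)
    gf <- matrix(rbinom(n * v, 2, f), n, v)
    tm <- matrix(rbinom(n * v, 1, gm / 2), n, v)
    tf <- matrix(rbinom(n * v, 1, gf / 2), n, v)
    gc <- tm + tf
    ids <- if (n) cohort$proband_id else character(0)
    dimnames(gc) <- dimnames(gm) <- dimnames(gf) <-
      list(ids, sprintf("v%04d", seq_len(v)))
    raw <- function(g) as.numeric(g %*% tp$weights)
    std <- function(x) {
      s <- sd(x)
      if (!is.finite(s) || s == 0) return(x - mean(x))
      (x - mean(x)) / s
    }
    sc <- data.frame(child = std(raw(gc)), mother = std(raw(gm)),
                     father = std(raw(gf)))
    phen <- tp$beta_direct * sc$child +
      tp$beta_parental * (sc$mother + sc$father) +
      rnorm(n, 0, tp$noise_sd)
    list(dosages = list(child = gc, mother = gm, father = gf),
         nontransmitted = list(mother = gm - tm, father = gf - tf),
         scores = sc, phenotype = phen)
  })
}

#' Simulate developmental milestone attainment times
#'
#' Event times are exponential: the baseline rate is `log(2) / median`
#' (months) per milestone, multiplied by `exp(log HR)` for the proband's
#' gestational age group and diagnosis. Observations are independently
#' right-censored with probability `censor_prob`, at a time uniform on
#' (0, event time).
#'
#' @param cohort A cohort table.
#' @param config A [sim_config] whose `milestone_params` are used.
#' @return `cohort` with, per milestone `m`, columns `ms_<m>_months`
#'   (observed time) and `ms_<m>_event` (1 = attained, 0 = censored).
#' @export
simulate_milestones <- function(cohort, config) {
  mp <- config$milestone_params
  if (any(mp$baseline_median_months <= 0))
    stop_config("baseline_median_months must be > 0")
  n <- nrow(cohort)
  lhr_cat <- c(term = 0, mp$log_hr_by_category)[
    as.character(cohort$prematurity_category)]
  with_substream(config$seed, "milestone", {
    for (m in names(mp$baseline_median_months)) {
      rate <- (log(2) / mp$baseline_median_months[[m]]) *
        exp(lhr_cat + mp$log_hr_diagnosis * cohort$diagnosed)
      t_event <- rexp(n, rate)
      censored <- rbinom(n, 1, mp$censor_prob) == 1
      obs <- ifelse(censored, runif(n) * t_event, t_event)
      cohort[[paste0("ms_", m, "_months")]] <- obs
      cohort[[paste0("ms_", m, "_event")]] <- as.integer(!censored)
    }
    cohort
  })
}

#' Simulate a rare-variant annotation table
#'
#' Emits, per proband, `n_variants_per_proband` candidate rare variants with
#' every field the burden-score filter cascade consumes. A configurable
#' fraction passes every filter; each failing variant has exactly one filter
#' broken, chosen uniformly, so the generator also exercises each rejection
#' path.
#'
#' @param cohort A cohort table.
#' @param n_genes Number of distinct (pLI-intolerant) genes to draw from.
#' @param seed Integer seed.
#' @param n_variants_per_proband Variants emitted per proband.
#' @param pass_fraction Probability a variant passes the full cascade.
#' @return Data frame with columns `proband_id`, `gene`, `consequence`,
#'   `loftee_confidence`, `mpc`, `pli`, `gnomad_max_maf`, `cohort_maf`,
#'   `inherited`, `autosomal`, `zygosity`.
#' @export
simulate_rare_variants <- function(cohort, n_genes, seed,
                                   n_variants_per_proband = 5,
                                   pass_fraction = 0.5) {
  if (n_genes < 1) stop_config("n_genes must be >= 1")
  if (pass_fraction < 0 || pass_fraction > 1)
    stop_config("pass_fraction must lie in [0, 1]")
  n <- nrow(cohort) * n_variants_per_proband
  with_substream(seed, "rare", {
    tab <- data.frame(
      proband_id = rep(cohort$proband_id, each = n_variants_per_proband),
      gene = sprintf("G%04d", sample.int(n_genes, n, replace = TRUE)),
      consequence = sample(c("ptv", "missense"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    tab$loftee_confidence <- ifelse(tab$consequence == "ptv", "HC", NA)
    tab$mpc <- ifelse(tab$consequence == "missense", runif(n, 2, 4), NA)
    tab$pli <- runif(n, 0.95, 1)
    tab$gnomad_max_maf <- runif(n, 0, 5e-6)
    tab$cohort_maf <- runif(n, 0, 5e-5)
    tab$inherited <- TRUE
    tab$autosomal <- TRUE
    tab$zygosity <- "het"
    fail <- runif(n) >= pass_fraction
    breaker <- sample.int(6, n, replace = TRUE)
    brk <- function(which, sel) fail & breaker == which & sel
    i <- brk(1, rep(TRUE, n)); tab$pli[i] <- runif(sum(i), 0, 0.9)
    i <- brk(2, rep(TRUE, n)); tab$gnomad_max_maf[i] <- runif(sum(i), 2e-5, 1e-3)
    i <- brk(3, rep(TRUE, n)); tab$cohort_maf[i] <- runif(sum(i), 2e-4, 1e-3)
    i <- brk(4, rep(TRUE, n)); tab$inherited[i] <- FALSE
    i <- brk(5, rep(TRUE, n)); tab$zygosity[i] <- "hom"
    i <- fail & breaker == 6
    tab$loftee_confidence[i & tab$consequence == "ptv"] <- "LC"
    j <- i & tab$consequence == "missense"
    tab$mpc[j] <- runif(sum(j), 0, 1.99)
    tab
  })
}
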