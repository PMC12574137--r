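DNM_CLASSES <- c("synonymous", "missense", "ptv")
NONSYN_CLASSES <- c("missense", "ptv")

validate_gene_rates <- function(rates) {
  need <- c("gene", "class", "mu")
  if (!all(need %in% names(rates)))
    stop_data("gene rate table needs columns: ", paste(need, collapse = ", "))
  if (any(!rates$class %in% DNM_CLASSES))
    stop_data("rate classes must be in {",
              paste(DNM_CLASSES, collapse = ", "), "}")
  if (any(!is.finite(rates$mu)) || any(rates$mu < 0))
    stop_data("mutation rates must be finite and >= 0")
  rates
}

#' Read a per-gene mutation-rate table
#'
#' @param path TSV with columns `gene`, `class`
#'   (`synonymous`/`missense`/`ptv`), `mu` (expected de novo mutations of
#'   that class in that gene per proband), and optionally `ddg2p`
#'   (logical gene-set tag).
#' @return Validated data frame.
#' @export
read_gene_rates <- function(path) {
  rates <- read_tsv(path)
  if ("ddg2p" %in% names(rates)) rates$ddg2p <- as.logical(rates$ddg2p)
  validate_gene_rates(rates)
}

#' Expected de novo mutation count under the null mutational model
#'
#' `E = n_probands * sum over genes in the set and requested classes of the
#' per-gene, per-class rate`.
#'
#' @param rates Gene rate table (see [read_gene_rates]).
#' @param n_probands Number of probands the expectation scales to.
#' @param gene_set Character vector of gene IDs (must all be in `rates`).
#' @param classes Consequence classes to sum over.
#' @return Numeric scalar expectation.
#' @export
expected_dnm_counts <- function(rates, n_probands, gene_set = unique(rates$gene),
                                classes = NONSYN_CLASSES) {
  rates <- validate_gene_rates(rates)
  unknown <- setdiff(gene_set, rates$gene)
  if (length(unknown))
    stop_data("genes absent from rate table: ",
              paste(utils::head(unknown, 5), collapse = ", "))
  sel <- rates$gene %in% gene_set & rates$class %in% classes
  n_probands * sum(rates$mu[sel])
}

#' Synonymous calibration factor for the null mutational model
#'
#' `lambda = O_synonymous / E_synonymous`, computed over **all** probands
#' (both gestational age groups pooled): synonymous mutations are assumed
#' phenotypically neutral, so their observed/expected ratio calibrates
#' technical deviations of the mutational model from the study's detection
#' pipeline.
#'
#' @param dnms DNM table with columns `proband_id`, `gene`, `class`.
#' @param rates Gene rate table.
#' @param n_probands Total proband count behind `dnms`.
#' @return Numeric `lambda` (> 0 normally; 0 with a warning when no
#'   synonymous DNMs are observed).
#' @export
synonymous_correction_factor <- function(dnms, rates, n_probands) {
  e_syn <- expected_dnm_counts(rates, n_probands, classes = "synonymous")
  if (e_syn <= 0) stop_data("synonymous expectation is zero; cannot calibrate")
  o_syn <- sum(dnms$class == "synonymous")
  if (o_syn == 0)
    warning("no synonymous DNMs observed; lambda = 0 is degenerate")
  o_syn / e_syn
}

#' One-sided exact Poisson test for a mutation-count excess
#'
#' `p = P(X >= O)` for `X ~ Poisson(E_corrected)` — the probability of
#' observing at least the observed count under the (calibrated) null
#' expectation.
#'
#' @param observed Observed count (non-negative integer).
#' @param expected_corrected Null mean (after any lambda correction).
#' @return p-value in (0, 1].
#' @export
poisson_excess_test <- function(observed, expected_corrected) {
  if (observed < 0) stop_data("observed count must be >= 0")
  if (expected_corrected <= 0) stop_data("expected count must be > 0")
  ppois(observed - 1, expected_corrected, lower.tail = FALSE)
}

#' Attributable fraction of cases due to nonsynonymous de novo mutations
#'
#' `AF = (O_nonsynonymous - lambda * E_nonsynonymous) / N_probands`: the
#' excess of observed over calibrated-expected nonsynonymous mutations,
#' per proband — interpreted as the proportion of cases attributable to
#' de novo mutations under the assumption of at most one causal mutation
#' per explained case. The uncertainty treats the observed count as Poisson
#' with the calibrated expectation fixed, `SE = sqrt(O) / N`, with a normal
#' 95% interval; a nonparametric bootstrap over probands is available as an
#' alternative.
#'
#' @param o_nonsyn Observed nonsynonymous count.
#' @param e_nonsyn Expected nonsynonymous count (uncalibrated).
#' @param lambda Synonymous calibration factor.
#' @param n_probands Probands in the stratum.
#' @return List with `af`, `se`, `ci` (length-2 vector).
#' @export
attributable_fraction <- function(o_nonsyn, e_nonsyn, lambda, n_probands) {
  if (n_probands <= 0) stop_data("n_probands must be > 0")
  if (lambda < 0) stop_data("lambda must be >= 0")
  af <- (o_nonsyn - lambda * e_nonsyn) / n_probands
  se <- sqrt(o_nonsyn) / n_probands
  list(af = af, se = se, ci = af + c(-1, 1) * qnorm(0.975) * se)
}

#' Compare attributable fractions between two strata
#'
#' Two-sided z-test: `z = (AF1 - AF2) / sqrt(SE1^2 + SE2^2)`. The caller is
#' responsible for the multiplicity ledger (nine tests when comparing three
#' proband groups across three gene sets).
#'
#' @param res1,res2 Lists with `af` and `se` (as from
#'   [attributable_fraction]).
#' @return List with `z` and two-sided normal `p`.
#' @export
compare_attributable_fractions <- function(res1, res2) {
  if (is.null(res1$se) || is.null(res2$se) ||
      !is.finite(res1$se) || !is.finite(res2$se))
    stop_data("both attributable fractions need finite standard errors")
  z <- (res1$af - res2$af) / sqrt(res1$se^2 + res2$se^2)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Stratified de novo burden and attributable-fraction analysis
#'
#' Runs the full battery: observed and expected nonsynonymous counts,
#' exact Poisson excess tests and attributable fractions in every stratum of
#' gestational age group (term/preterm) by proband group
#' (all/diagnosed/undiagnosed) by gene set (exome/DDG2P/non-DDG2P), with a
#' single synonymous calibration factor computed exome-wide over all
#' probands. Attributable fractions are compared term vs preterm per proband
#' group and gene set with z-tests. Both Bonferroni ledgers (18 Poisson
#' tests; 9 AF comparisons) are attached.
#'
#' @param cohort Cohort table with `proband_id`, `prematurity_category`,
#'   `diagnosed`.
#' @param dnms DNM table (`proband_id`, `gene`, `class`).
#' @param rates Gene rate table; DDG2P membership is taken from its `ddg2p`
#'   column unless `ddg2p_genes` is given.
#' @param ddg2p_genes Optional character vector of DD-associated genes.
#' @param apply_lambda Test observed counts against `lambda * E` (default)
#'   rather than raw `E`.
#' @return Object of class `dnm_burden`: list with `lambda`, `strata` (data
#'   frame of O, E, p, AF, SE, CI per stratum), `comparisons` (term vs
#'   preterm z-tests) and the Bonferroni ledgers.
#' @export
run_dnm_analysis <- function(cohort, dnms, rates, ddg2p_genes = NULL,
                             apply_lambda = TRUE) {
  rates <- validate_gene_rates(rates)
  if (is.null(ddg2p_genes)) {
    if (!"ddg2p" %in% names(rates))
      stop_config("supply ddg2p_genes or a ddg2p column in the rate table")
    ddg2p_genes <- unique(rates$gene[rates$ddg2p])
  }
  unresolved <- setdiff(dnms$proband_id, cohort$proband_id)
  if (length(unresolved))
    stop_data(length(unresolved), " DNM proband IDs not in cohort")
  all_genes <- unique(rates$gene)
  gene_sets <- list(exome = all_genes,
                    ddg2p = intersect(ddg2p_genes, all_genes),
                    non_ddg2p = setdiff(all_genes, ddg2p_genes))
  n_all <- nrow(cohort)
  lambda <- synonymous_correction_factor(dnms, rates, n_all)

  preterm <- cohort$prematurity_category != "term"
  groups <- list(term = !preterm, preterm = preterm)
  proband_groups <- list(
    all = rep(TRUE, n_all),
    diagnosed = cohort$diagnosed == 1,
    undiagnosed = cohort$diagnosed == 0)

  dnm_nonsyn <- dnms[dnms$class %in% NONSYN_CLASSES, , drop = FALSE]
  rows <- list(); comps <- list()
  for (pg in names(proband_groups)) for (gs in names(gene_sets)) {
    per_group <- lapply(names(groups), function(g) {
      sel <- groups[[g]] & proband_groups[[pg]]
      ids <- cohort$proband_id[sel]
      n <- length(ids)
      o <- sum(dnm_nonsyn$proband_id %in% ids &
                 dnm_nonsyn$gene %in% gene_sets[[gs]])
      e <- expected_dnm_counts(rates, n, gene_sets[[gs]], NONSYN_CLASSES)
      if (n == 0 || e == 0)
        return(list(stratum = g, n = n, O = o, E = e, p = NA_real_,
                    af = NA_real_, se = NA_real_, lo = NA_real_,
                    hi = NA_real_, flagged = TRUE))
      p <- poisson_excess_test(o, if (apply_lambda) lambda * e else e)
      af <- attributable_fraction(o, e, lambda, n)
      list(stratum = g, n = n, O = o, E = e, p = p, af = af$af, se = af$se,
           lo = af$ci[1], hi = af$ci[2], flagged = FALSE)
    })
    names(per_group) <- names(groups)
    for (g in names(groups)) {
      r <- per_group[[g]]
      rows[[length(rows) + 1L]] <- data.frame(
        gestation = g, proband_group = pg, gene_set = gs, n_probands = r$n,
        observed = r$O, expected = r$E, lambda = lambda, excess_p = r$p,
        af = r$af, af_se = r$se, af_lo = r$lo, af_hi = r$hi,
        flagged = r$flagged, stringsAsFactors = FALSE)
    }
    tt <- per_group$term; pp <- per_group$preterm
    cmp <- if (tt$flagged || pp$flagged) list(z = NA_real_, p = NA_real_)
      else compare_attributable_fractions(list(af = tt$af, se = tt$se),
                                          list(af = pp$af, se = pp$se))
    comps[[length(comps) + 1L]] <- data.frame(
      proband_group = pg, gene_set = gs, af_term = tt$af, af_preterm = pp$af,
      z = cmp$z, p = cmp$p, stringsAsFactors = FALSE)
  }
  strata <- do.call(rbind, rows)
  comparisons <- do.call(rbind, comps)
  structure(list(lambda = lambda, strata = strata, comparisons = comparisons,
                 apply_lambda = apply_lambda,
                 ledgers = list(
                   poisson = list(n_tests = nrow(strata),
                                  threshold = bonferroni_threshold(nrow(strata))),
                   af_comparison = list(n_tests = nrow(comparisons),
                                        threshold = bonferroni_threshold(nrow(comparisons))))),
            class = "dnm_burden")
}

#' @export
print.dnm_burden <- function(x, digits = 3, ...) {
  cat("De novo mutation burden analysis\n")
  cat("  synonymous calibration lambda =", format(x$lambda, digits = digits),
      if (x$apply_lambda) "(applied in Poisson tests)" else "(not applied)", "\n")
  cat("  Poisson ledger:", x$ledgers$poisson$n_tests, "tests, threshold",
      format(x$ledgers$poisson$threshold, digits = 3), "\n\n")
  s <- x$strata
  s$expected <- round(s$expected, 1)
  s$af <- round(s$af, 3); s$af_lo <- round(s$af_lo, 3)
  s$af_hi <- round(s$af_hi, 3)
  s$excess_p <- signif(s$excess_p, 2)
  print(s[c("gestation", "proband_group", "gene_set", "n_probands",
            "observed", "expected", "excess_p", "af", "af_lo", "af_hi")],
        row.names = FALSE)
  cat("\nTerm vs preterm attributable-fraction z-tests (ledger:",
      x$ledgers$af_comparison$n_tests, "tests):\n")
  cmp <- x$comparisons
  cmp$z <- round(cmp$z, 2); cmp$p <- signif(cmp$p, 2)
  cmp$af_term <- round(cmp$af_term, 3); cmp$af_preterm <- round(cmp$af_preterm, 3)
  print(cmp, row.names = FALSE)
  invisible(x)
}

#' Bootstrap attributable-fraction uncertainty over probands
#'
#' Alternative to the Poisson-count standard error: resample probands with
#' replacement, recompute the attributable fraction on each resample (lambda
#' held fixed), and report the bootstrap SE and percentile interval.
#'
#' @param dnms DNM table restricted to the stratum of interest.
#' @param proband_ids Proband IDs in the stratum.
#' @param rates Gene rate table.
#' @param gene_set Gene set defining the numerator.
#' @param lambda Fixed calibration factor.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @return List with `af`, `se`, `ci`.
#' @export
attributable_fraction_boot <- function(dnms, proband_ids, rates, gene_set,
                                       lambda, n_boot = 500, seed = 1) {
  n <- length(proband_ids)
  if (n == 0) stop_data("empty stratum")
  e1 <- expected_dnm_counts(rates, 1, gene_set, NONSYN_CLASSES)
  sel <- dnms$class %in% NONSYN_CLASSES & dnms$gene %in% gene_set
  counts <- table(factor(dnms$proband_id[sel], levels = proband_ids))
  af_hat <- (sum(counts) - lambda * e1 * n) / n
  with_substream(seed, "afboot", {
    reps <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      (sum(counts[idx]) - lambda * e1 * n) / n
    }, numeric(1))
    list(af = af_hat, se = sd(reps),
         ci = unname(quantile(reps, c(0.025, 0.975))))
  })
}
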