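#' Select genes testable for a prematurity association
#'
#' Genes whose observed diagnostic-variant count meets the minimum are
#' testable; the threshold reflects power: with ~1000 preterm probands among
#' ~7500 single-gene diagnoses, 30+ carriers gives adequate power for odds
#' ratios of six or higher.
#'
#' @param diag Diagnosis table: one row per diagnosed proband with columns
#'   `proband_id`, `gene`, `preterm` (0/1) and optionally `tier`.
#' @param min_count Minimum diagnostic-variant count (default 30).
#' @return Character vector of gene IDs, sorted by count (desc) then ID.
#' @export
select_testable_genes <- function(diag, min_count = 30) {
  if (!nrow(diag)) return(character(0))
  counts <- table(diag$gene)
  counts <- counts[counts >= min_count]
  names(counts)[order(-as.integer(counts), names(counts))]
}

# Closed-form 2x2 log-OR and Wald SE; identical to the logistic-regression
# MLE and Wald test when the only predictor is the carrier indicator.
logor_wald_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) == 0))
    return(list(logor = NA_real_, se = NA_real_, p = NA_real_,
                degenerate = TRUE))
  logor <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(logor = logor, se = se, p = 2 * pnorm(-abs(logor / se)),
       degenerate = FALSE)
}

#' Per-gene association between a monogenic diagnosis and prematurity
#'
#' Among diagnosed probands with single-gene diagnoses, logistic regression
#' of prematurity (binary) on the indicator for a diagnosis in `gene`.
#' When a cell of the implied 2x2 table is empty (separation), the model is
#' inestimable: the result falls back to Fisher's exact test with the
#' conditional-MLE odds ratio and is flagged.
#'
#' @param diag Diagnosis table (see [select_testable_genes]).
#' @param gene Gene ID to test.
#' @param confirmed_only Restrict to rows with `tier == "confirmed"`
#'   (clinically annotated pathogenic/likely pathogenic) for the sensitivity
#'   analysis.
#' @param cohort_covariate Optionally adjust for a `cohort_label` column.
#' @return One-row data frame: `gene`, `or`, `logor`, `se`, `p`, counts, and
#'   `method` (`"logistic"` or `"fisher"`).
#' @export
per_gene_prematurity_association <- function(diag, gene,
                                             confirmed_only = FALSE,
                                             cohort_covariate = FALSE) {
  if (confirmed_only) diag <- diag[diag$tier == "confirmed", , drop = FALSE]
  carrier <- as.integer(diag$gene == gene)
  preterm <- as.integer(diag$preterm)
  a <- sum(carrier == 1 & preterm == 1); b <- sum(carrier == 1 & preterm == 0)
  c_ <- sum(carrier == 0 & preterm == 1); d <- sum(carrier == 0 & preterm == 0)
  if (min(a, b, c_, d) == 0) {
    ft <- fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
    return(data.frame(gene = gene, or = unname(ft$estimate),
                      logor = NA_real_, se = NA_real_, p = ft$p.value,
                      n_carriers = a + b, n = length(carrier),
                      preterm_carriers = a, method = "fisher",
                      stringsAsFactors = FALSE))
  }
  f <- if (cohort_covariate) preterm ~ carrier + cohort else preterm ~ carrier
  dat <- data.frame(preterm = preterm, carrier = carrier,
                    cohort = diag$cohort_label %||% "all")
  fit <- glm(f, data = dat, family = binomial())
  co <- summary(fit)$coefficients["carrier", ]
  data.frame(gene = gene, or = exp(co[1]), logor = unname(co[1]),
             se = unname(co[2]), p = unname(co[4]),
             n_carriers = a + b, n = length(carrier), preterm_carriers = a,
             method = "logistic", stringsAsFactors = FALSE)
}

#' Gene-set enrichment of monogenic diagnoses across gestational age groups
#'
#' For each gene set: an overall k-by-2 Fisher's exact test of whether the
#' proportion of diagnosed probands carrying a diagnosis in the set differs
#' across gestational age groups (term / moderately preterm / very-or-
#' extremely preterm, the pooled scheme used because very and extreme groups
#' are small), followed by post hoc pairwise 2x2 exact tests of each preterm
#' group against term, with conditional-MLE odds ratios. The multiplicity
#' ledger counts (1 overall + pairwise) tests per set.
#'
#' @param diag Diagnosis table with `gene` and `prematurity_category`.
#' @param gene_sets Named list of gene-ID vectors (e.g. from [read_gmt]).
#' @param pairwise `"vs_term"` (default: each preterm group against term) or
#'   `"all"` (all pairs).
#' @return List of class `gene_set_enrichment`: `overall` (per-set k-by-2
#'   test), `pairwise` (per-set, per-contrast 2x2 tests) and `ledger`.
#' @export
gene_set_fisher <- function(diag, gene_sets, pairwise = c("vs_term", "all")) {
  pairwise <- match.arg(pairwise)
  grp <- as.character(diag$prematurity_category)
  grp[grp %in% c("very", "extreme")] <- "very_or_extreme"
  grp <- factor(grp, levels = c("term", "moderate", "very_or_extreme"))
  grp <- droplevels(grp)
  if (nlevels(grp) < 2) stop_data("need >= 2 non-empty gestational groups")
  overall <- list(); pw <- list()
  for (set_name in names(gene_sets)) {
    in_set <- diag$gene %in% gene_sets[[set_name]]
    tab <- table(grp, factor(in_set, levels = c(TRUE, FALSE)))
    empty <- any(rowSums(tab) == 0)
    p_overall <- if (empty) NA_real_ else fisher.test(tab)$p.value
    overall[[set_name]] <- data.frame(
      gene_set = set_name, n_groups = nlevels(grp),
      n_in_set = sum(in_set), p = p_overall, flagged = empty,
      stringsAsFactors = FALSE)
    lv <- levels(grp)
    contrasts <- if (pairwise == "vs_term")
      lapply(setdiff(lv, "term"), function(g) c(g, "term"))
    else utils::combn(lv, 2, simplify = FALSE)
    for (ct in contrasts) {
      sel <- grp %in% ct
      t2 <- table(factor(grp[sel], levels = ct),
                  factor(in_set[sel], levels = c(TRUE, FALSE)))
      if (any(rowSums(t2) == 0)) {
        pw[[length(pw) + 1L]] <- data.frame(
          gene_set = set_name, group = ct[1], reference = ct[2],
          or = NA_real_, or_lo = NA_real_, or_hi = NA_real_, p = NA_real_,
          flagged = TRUE, stringsAsFactors = FALSE)
        next
      }
      ft <- fisher.test(t2)
      pw[[length(pw) + 1L]] <- data.frame(
        gene_set = set_name, group = ct[1], reference = ct[2],
        or = unname(ft$estimate), or_lo = ft$conf.int[1],
        or_hi = ft$conf.int[2], p = ft$p.value, flagged = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  overall <- do.call(rbind, overall)
  pw <- do.call(rbind, pw)
  n_tests <- nrow(overall) + nrow(pw)
  structure(list(overall = overall, pairwise = pw,
                 ledger = list(n_tests = n_tests,
                               threshold = bonferroni_threshold(n_tests))),
            class = "gene_set_enrichment")
}

#' @export
print.gene_set_enrichment <- function(x, ...) {
  cat("Gene-set enrichment of monogenic diagnoses\n")
  cat(sprintf("  ledger: %d tests, Bonferroni threshold %.3g\n\n",
              x$ledger$n_tests, x$ledger$threshold))
  ov <- x$overall; ov$p <- signif(ov$p, 3)
  print(ov, row.names = FALSE)
  cat("\nPairwise contrasts:\n")
  pwt <- x$pairwise
  pwt$or <- round(pwt$or, 2); pwt$p <- signif(pwt$p, 3)
  print(pwt[c("gene_set", "group", "reference", "or", "p")], row.names = FALSE)
  invisible(x)
}

#' Monte-Carlo power of the per-gene prematurity test
#'
#' Simulates cohorts of diagnosed probands in which `carriers` probands
#' carry a diagnosis in the focal gene and prematurity follows the given
#' baseline fraction in non-carriers and the odds-ratio-shifted fraction in
#' carriers, then applies the per-gene test (closed-form Wald on the 2x2
#' table, identical to the logistic Wald test for a single binary
#' predictor; Fisher's exact on separation) and reports the fraction of
#' replicates significant at `alpha`.
#'
#' @param n_diagnosed Total diagnosed probands per replicate.
#' @param carriers Carriers of the focal gene per replicate.
#' @param baseline_preterm_frac Preterm fraction in non-carriers.
#' @param or True carrier odds ratio for prematurity.
#' @param alpha Significance level (e.g. `0.05 / 44`).
#' @param n_sims Replicates.
#' @param seed Integer seed.
#' @return Estimated power in `[0, 1]`.
#' @export
power_to_detect <- function(n_diagnosed, carriers, baseline_preterm_frac,
                            or, alpha, n_sims = 500, seed = 1) {
  stopifnot(baseline_preterm_frac > 0, baseline_preterm_frac < 1,
            or > 0, alpha > 0, alpha < 1)
  if (carriers == 0) return(0)
  odds0 <- baseline_preterm_frac / (1 - baseline_preterm_frac)
  p1 <- or * odds0 / (1 + or * odds0)
  n_non <- n_diagnosed - carriers
  with_substream(seed, "power", {
    hits <- vapply(seq_len(n_sims), function(i) {
      a <- rbinom(1, carriers, p1)
      c_ <- rbinom(1, n_non, baseline_preterm_frac)
      w <- logor_wald_2x2(a, carriers - a, c_, n_non - c_)
      p <- if (w$degenerate)
        fisher.test(matrix(c(a, carriers - a, c_, n_non - c_), 2,
                           byrow = TRUE))$p.value
      else w$p
      p < alpha
    }, logical(1))
    mean(hits)
  })
}
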