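MISSENSE_LIKE_CONSEQUENCES <- c("missense", "stop_lost", "start_lost",
                                "inframe_insertion", "inframe_deletion")

#' Read a polygenic scoring file
#'
#' Tab-separated file following the PGS-Catalog column convention:
#' `variant_id`, `effect_allele`, `other_allele`, `weight`.
#'
#' @param path Path to the scoring file.
#' @return Validated data frame.
#' @export
read_scoring_file <- function(path) {
  w <- read_tsv(path)
  need <- c("variant_id", "effect_allele", "other_allele", "weight")
  if (!all(need %in% names(w)))
    stop_data("scoring file needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(w$variant_id)) stop_data("duplicate variant IDs")
  if (any(!is.finite(w$weight))) stop_data("weights must be finite")
  w
}

#' Compute polygenic scores as weighted dosage sums
#'
#' The score is the weighted sum of effect-allele dosages over the variants
#' shared between the dosage matrix and the scoring file. Alleles are
#' matched by variant ID plus exact allele pair: a swapped effect/other pair
#' flips the dosage to `2 - d`; a mismatched pair is dropped with a warning
#' (inputs are assumed strand-harmonised upstream). Missing dosages are
#' imputed to twice the effect-allele frequency computed from non-missing
#' carriers. Raw scores are standardised (mean 0, SD 1) within cohort.
#'
#' @param dosages Numeric matrix, individuals x variants, effect-allele
#'   dosages in `[0, 2]` (NA allowed); column names are variant IDs.
#' @param weights Scoring data frame (see [read_scoring_file]).
#' @param dosage_alleles Optional data frame (`variant_id`, `effect_allele`,
#'   `other_allele`) describing which allele the dosages count; when `NULL`
#'   the dosages are assumed aligned to the scoring file's effect alleles.
#' @param cohort Cohort labels for within-cohort standardisation (recycled).
#' @return Data frame with `individual_id`, `raw_score`, `score`
#'   (standardised), and an attribute `n_variants` (matched variants).
#' @export
compute_pgs <- function(dosages, weights, dosage_alleles = NULL,
                        cohort = "all") {
  stopifnot(is.matrix(dosages))
  if (any(dosages < 0 | dosages > 2, na.rm = TRUE))
    stop_data("dosages must lie in [0, 2]")
  shared <- intersect(colnames(dosages), weights$variant_id)
  if (!length(shared)) stop_data("no overlapping variants between dosages and weights")
  d <- dosages[, shared, drop = FALSE]
  w <- weights[match(shared, weights$variant_id), ]
  if (!is.null(dosage_alleles)) {
    da <- dosage_alleles[match(shared, dosage_alleles$variant_id), ]
    same <- da$effect_allele == w$effect_allele &
      da$other_allele == w$other_allele
    swapped <- da$effect_allele == w$other_allele &
      da$other_allele == w$effect_allele
    mismatch <- !(same | swapped)
    if (any(mismatch)) {
      warning(sum(mismatch), " variant(s) dropped: allele pair mismatch")
      d <- d[, !mismatch, drop = FALSE]
      w <- w[!mismatch, , drop = FALSE]
      swapped <- swapped[!mismatch]
    }
    if (any(swapped)) d[, swapped] <- 2 - d[, swapped]
    if (!ncol(d)) stop_data("no variants left after allele matching")
  }
  # mean imputation of missing dosages = 2 x effect-allele frequency
  for (j in seq_len(ncol(d))) {
    miss <- is.na(d[, j])
    if (any(miss)) d[miss, j] <- mean(d[!miss, j])
  }
  raw <- as.numeric(d %*% w$weight)
  cohort <- rep_len(as.character(cohort), nrow(d))
  score <- numeric(length(raw))
  for (cc in unique(cohort)) {
    sel <- cohort == cc
    s <- sd(raw[sel])
    score[sel] <- if (!is.finite(s) || s == 0) raw[sel] - mean(raw[sel])
                  else (raw[sel] - mean(raw[sel])) / s
  }
  out <- data.frame(individual_id = rownames(d) %||% seq_along(raw),
                    raw_score = raw, score = score,
                    stringsAsFactors = FALSE)
  attr(out, "n_variants") <- ncol(d)
  out
}

#' Which rare variants pass the deleterious burden-score filter cascade?
#'
#' A variant counts towards the rare variant burden score iff it is
#' autosomal, heterozygous, inherited, either a high-confidence
#' protein-truncating variant or a missense-like variant (missense,
#' stop/start lost, inframe indel, or low-confidence loss-of-function) with
#' MPC >= 2, in a loss-of-function-intolerant gene (pLI > 0.9), with
#' MAF < 1e-5 in every gnomAD super-population and cohort MAF < 1e-4.
#'
#' @param variants Variant annotation table (see
#'   [simulate_rare_variants] for the schema).
#' @return Logical vector, one element per variant row.
#' @export
rvbs_pass <- function(variants) {
  need <- c("proband_id", "gene", "consequence", "loftee_confidence", "mpc",
            "pli", "gnomad_max_maf", "cohort_maf", "inherited", "autosomal",
            "zygosity")
  missing_cols <- setdiff(need, names(variants))
  if (length(missing_cols))
    stop_data("variant table missing columns: ",
              paste(missing_cols, collapse = ", "))
  hc_ptv <- variants$consequence == "ptv" &
    !is.na(variants$loftee_confidence) & variants$loftee_confidence == "HC"
  missense_like <- variants$consequence %in% MISSENSE_LIKE_CONSEQUENCES |
    (variants$consequence == "ptv" &
       !is.na(variants$loftee_confidence) & variants$loftee_confidence == "LC")
  damaging <- hc_ptv |
    (missense_like & !is.na(variants$mpc) & variants$mpc >= 2)
  variants$autosomal & variants$zygosity == "het" & variants$inherited &
    damaging & variants$pli > 0.9 &
    variants$gnomad_max_maf < 1e-5 & variants$cohort_maf < 1e-4
}

#' Rare variant burden score per proband
#'
#' Counts, per proband, the variants passing the [rvbs_pass] cascade.
#'
#' @param variants Variant annotation table.
#' @param proband_ids Probands to report (default: those in the table);
#'   probands with no qualifying variant score 0.
#' @return Named integer vector of burden scores.
#' @export
compute_rvbs <- function(variants, proband_ids = NULL) {
  pass <- rvbs_pass(variants)
  ids <- proband_ids %||% sort(unique(variants$proband_id))
  counts <- table(factor(variants$proband_id[pass], levels = ids))
  setNames(as.integer(counts), ids)
}

#' Rank-based inverse normal transformation
#'
#' Blom transform: `qnorm((rank - 3/8) / (n + 1/4))`, with average ranks for
#' ties and missing values propagated. Used to normalise gestational
#' duration before the score regressions.
#'
#' @param values Numeric vector (>= 2 non-missing, not all equal).
#' @return Transformed numeric vector.
#' @export
rint <- function(values) {
  ok <- !is.na(values)
  x <- values[ok]
  if (length(x) < 2) stop_data("need >= 2 non-missing values")
  if (length(unique(x)) < 2) stop_data("all values equal; transform undefined")
  r <- rank(x, ties.method = "average")
  out <- rep(NA_real_, length(values))
  out[ok] <- qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  out
}

#' Regression of gestational duration on a genetic score
#'
#' Linear regression of rank-inverse-normal-transformed gestational duration
#' on a standardised genetic score (polygenic or rare-variant burden),
#' adjusting for sex and the leading genetic principal components. The
#' coefficient reads as the change in SD of transformed gestational duration
#' per SD of score. The interaction form adds diagnostic status (0/1) and a
#' score-by-diagnosis term to test whether a monogenic diagnosis modifies
#' the association.
#'
#' @param outcome Gestational duration (raw; transformed internally unless
#'   `rint_outcome = FALSE`).
#' @param score Genetic score (standardised internally unless constant).
#' @param covariates Data frame: `sex` plus PC columns (20 expected by
#'   default; fewer allowed with `n_pcs`).
#' @param diagnosed Optional 0/1 vector; required when `interaction = TRUE`.
#' @param interaction Add diagnosis main effect and score x diagnosis.
#' @param rint_outcome Apply [rint] to the outcome (default `TRUE`).
#' @param n_pcs Number of `PC*` columns expected in `covariates`.
#' @return An `assoc_result` data frame (term, estimate, se, p, n, family,
#'   converged).
#' @export
gd_score_regression <- function(outcome, score, covariates, diagnosed = NULL,
                                interaction = FALSE, rint_outcome = TRUE,
                                n_pcs = 20) {
  pc_cols <- grep("^PC[0-9]+$", names(covariates), value = TRUE)
  if (length(pc_cols) != n_pcs)
    stop_data("expected ", n_pcs, " PC columns, found ", length(pc_cols),
              " (override with n_pcs)")
  y <- if (rint_outcome) rint(outcome) else outcome
  s <- sd(score, na.rm = TRUE)
  score_std <- if (is.finite(s) && s > 0)
    (score - mean(score, na.rm = TRUE)) / s else score
  dat <- data.frame(y = y, score = score_std, covariates)
  rhs <- c("score", "sex", pc_cols)
  if (interaction) {
    if (is.null(diagnosed)) stop_config("interaction form needs `diagnosed`")
    dat$diagnosed <- diagnosed
    rhs <- c(rhs, "diagnosed", "score:diagnosed")
  }
  dat <- dat[complete.cases(dat), , drop = FALSE]
  fit <- lm(as.formula(paste("y ~", paste(rhs, collapse = " + "))), data = dat)
  if (any(is.na(coef(fit)))) stop_data("design matrix is rank-deficient")
  res <- extract_assoc(fit, nrow(dat), "continuous")
  class(res) <- c("assoc_result", "data.frame")
  res
}

#' Trio decomposition of direct and parental polygenic effects
#'
#' Joint regression of the child's phenotype on the child's, mother's and
#' father's polygenic scores (plus optional covariates). Conditional on the
#' parental scores, the child's score varies only through Mendelian
#' segregation, so the child coefficient estimates the direct genetic
#' effect; the parental coefficients capture the association of
#' non-transmitted parental alleles with the child's phenotype (indirect
#' genetic effects or confounding). The `"nontransmitted"` parameterisation
#' regresses on the child score and the combined non-transmitted score
#' `mother + father - child` (raw scale); its child coefficient equals
#' direct + non-transmitted effects summed differently but spans the same
#' model space.
#'
#' @param child,mother,father Numeric polygenic scores (standardised
#'   internally).
#' @param phenotype Numeric outcome.
#' @param covariates Optional data frame of additional covariates.
#' @param parameterisation `"parental"` (default) or `"nontransmitted"`.
#' @return An `assoc_result` data frame.
#' @export
trio_decomposition <- function(child, mother, father, phenotype,
                               covariates = NULL,
                               parameterisation = c("parental",
                                                    "nontransmitted")) {
  parameterisation <- match.arg(parameterisation)
  std <- function(x) {
    s <- sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(x - mean(x, na.rm = TRUE))
    (x - mean(x, na.rm = TRUE)) / s
  }
  # segregation variance check: the child score must not be an exact linear
  # combination of the parental scores
  seg <- lm(child ~ mother + father)
  if (var(residuals(seg)) < 1e-12)
    stop_data("child score collinear with parental scores; ",
              "no segregation variance to identify the direct effect")
  dat <- if (parameterisation == "parental")
    data.frame(phenotype = phenotype, child = std(child),
               mother = std(mother), father = std(father))
  else
    data.frame(phenotype = phenotype, child = std(child),
               nontransmitted = std(mother + father - child))
  rhs <- setdiff(names(dat), "phenotype")
  if (!is.null(covariates)) {
    dat <- cbind(dat, covariates)
    rhs <- c(rhs, names(covariates))
  }
  dat <- dat[complete.cases(dat), , drop = FALSE]
  fit <- lm(as.formula(paste("phenotype ~", paste(rhs, collapse = " + "))),
            data = dat)
  res <- extract_assoc(fit, nrow(dat), "continuous")
  class(res) <- c("assoc_result", "data.frame")
  res
}
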