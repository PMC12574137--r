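#' Specify a phenotype-on-prematurity regression model
#'
#' Encodes one member of the regression battery: which outcome, its family,
#' whether prematurity enters as three category dummies (vs term) or as
#' standardised continuous gestation, which covariate set applies (antenatal
#' outcomes adjust for maternal age at birth; all other outcomes adjust for
#' the proband's age at assessment and sex), and whether a diagnosis main
#' effect plus prematurity-by-diagnosis interaction is included. One
#' optional extra covariate (e.g. a deprivation index or a polygenic score)
#' can be added for sensitivity models.
#'
#' @param outcome Column name of the outcome.
#' @param family `"binary"` (logistic), `"continuous"` (linear) or `"count"`
#'   (negative binomial with Poisson fallback).
#' @param predictor `"category"` or `"continuous_gestation"`.
#' @param covariates `"antenatal"` (maternal age) or `"postnatal"`
#'   (proband age at assessment + sex).
#' @param diagnosis Include diagnosis main effect and
#'   prematurity-by-diagnosis interaction.
#' @param extra_covariate Optional single extra covariate column name.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(outcome,
                       family = c("binary", "continuous", "count"),
                       predictor = c("category", "continuous_gestation"),
                       covariates = c("postnatal", "antenatal"),
                       diagnosis = FALSE,
                       extra_covariate = NULL) {
  family <- match.arg(family)
  predictor <- match.arg(predictor)
  covariates <- match.arg(covariates)
  structure(list(outcome = outcome, family = family, predictor = predictor,
                 covariates = covariates, diagnosis = diagnosis,
                 extra_covariate = extra_covariate),
            class = "model_spec")
}

spec_formula <- function(spec) {
  prem <- if (spec$predictor == "category") "prematurity_category"
          else "gestation_std"
  covs <- if (spec$covariates == "antenatal") "maternal_age_years"
          else c("age_at_assessment_years", "sex")
  rhs <- c(prem, covs)
  if (spec$diagnosis) rhs <- c(rhs, "diagnosed", paste0(prem, ":diagnosed"))
  if (!is.null(spec$extra_covariate)) rhs <- c(rhs, spec$extra_covariate)
  as.formula(paste(spec$outcome, "~", paste(rhs, collapse = " + ")))
}

assoc_row <- function(term, estimate, se, p, n, family, converged = TRUE) {
  data.frame(term = term, estimate = estimate, se = se, p = p, n = n,
             family = family, converged = converged, stringsAsFactors = FALSE)
}

extract_assoc <- function(fit, n, family) {
  sm <- summary(fit)
  co <- if (inherits(fit, "lm") && !inherits(fit, "glm"))
    sm$coefficients else sm$coefficients
  est <- co[, 1]; se <- co[, 2]; p <- co[, 4]
  # NA coefficients (aliased terms, empty cells) are flagged, not dropped
  aliased <- is.na(coef(fit))
  terms_all <- names(coef(fit))
  out <- do.call(rbind, lapply(terms_all, function(tm) {
    if (aliased[[tm]])
      assoc_row(tm, NA_real_, NA_real_, NA_real_, n, family, FALSE)
    else {
      # separation / divergence: implausibly large logistic coefficients
      diverged <- family == "binary" &&
        (abs(est[[tm]]) > 15 || se[[tm]] > 100)
      assoc_row(tm, est[[tm]], se[[tm]], p[[tm]], n, family, !diverged)
    }
  }))
  out
}

#' Fit one phenotype-on-prematurity model
#'
#' Logistic regression for binary outcomes, linear regression for continuous
#' outcomes and negative binomial regression (maximum-likelihood dispersion)
#' for counts, with a Poisson fallback (warning) when the dispersion
#' estimate degenerates. Non-convergence, separation and inestimable terms
#' (empty category cells) are flagged in the result, never silently dropped.
#'
#' @param data Cohort table containing the outcome, predictors and
#'   covariates named by the spec.
#' @param spec A [model_spec].
#' @return Data frame of class `assoc_result`: one row per model term with
#'   `term`, `estimate` (log-odds, mean difference or log incidence-rate
#'   ratio), `se`, `p`, `n`, `family`, `converged`.
#' @export
fit_phenotype_model <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  f <- spec_formula(spec)
  vars <- all.vars(f)
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols))
    stop_data("columns missing from data: ",
              paste(missing_cols, collapse = ", "))
  data <- data[complete.cases(data[vars]), , drop = FALSE]
  n <- nrow(data)
  y <- data[[spec$outcome]]
  if (length(unique(y)) < 2L)
    stop_data("outcome '", spec$outcome, "' is constant; model is degenerate")
  if (spec$diagnosis && !any(data$diagnosed == 1))
    stop_data("no diagnosed probands; interaction is inestimable")
  fit <- switch(spec$family,
    binary = glm(f, data = data, family = binomial()),
    continuous = lm(f, data = data),
    count = tryCatch(
      suppressWarnings(MASS::glm.nb(f, data = data)),
      error = function(e) {
        warning("negative binomial dispersion estimation failed (",
                conditionMessage(e), "); falling back to Poisson")
        glm(f, data = data, family = poisson())
      }))
  res <- extract_assoc(fit, n, spec$family)
  class(res) <- c("assoc_result", "data.frame")
  attr(res, "spec") <- spec
  res
}

#' Fit the diagnosis-interaction form of a phenotype model
#'
#' Convenience wrapper: the same model as [fit_phenotype_model] with a
#' diagnosis main effect and a prematurity-by-diagnosis interaction added,
#' to test whether a monogenic diagnosis modifies the association between
#' prematurity and the outcome.
#'
#' @inheritParams fit_phenotype_model
#' @return An `assoc_result` including the interaction terms.
#' @export
fit_interaction_model <- function(data, spec) {
  spec$diagnosis <- TRUE
  fit_phenotype_model(data, spec)
}

#' Standardise gestational duration within cohort
#'
#' Centres and scales gestational duration to mean 0, SD 1 within each
#' cohort, so continuous-gestation coefficients read as change per one-SD
#' change in gestational duration.
#'
#' @param values Numeric gestational durations.
#' @param by_cohort Cohort labels, recycled if length 1.
#' @return Numeric vector of standardised values.
#' @export
standardise_gestation <- function(values, by_cohort = "all") {
  by_cohort <- rep_len(as.character(by_cohort), length(values))
  out <- numeric(length(values))
  for (cc in unique(by_cohort)) {
    sel <- by_cohort == cc
    v <- values[sel]
    s <- sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop_data("gestational duration constant within cohort '", cc, "'")
    out[sel] <- (v - mean(v, na.rm = TRUE)) / s
  }
  out
}

#' Fixed-effect inverse-variance-weighted meta-analysis of one term
#'
#' Pools per-cohort estimates of the same model term with weights
#' `w = 1/SE^2`: pooled beta is `sum(w * beta) / sum(w)`, pooled SE is
#' `1/sqrt(sum(w))`, with a two-sided normal p-value. Non-converged inputs
#' are dropped (it is an error if none remain).
#'
#' @param estimates Numeric per-cohort estimates.
#' @param ses Numeric per-cohort standard errors (> 0).
#' @param converged Logical vector (default all `TRUE`).
#' @return List of class `meta_result`: `estimate`, `se`, `p`, `n_studies`,
#'   `inputs`.
#' @export
ivw_meta <- function(estimates, ses, converged = rep(TRUE, length(estimates))) {
  keep <- converged & is.finite(estimates) & is.finite(ses) & ses > 0
  if (!any(keep)) stop_data("no converged inputs to meta-analyse")
  b <- estimates[keep]; s <- ses[keep]
  w <- 1 / s^2
  est <- sum(w * b) / sum(w)
  se <- 1 / sqrt(sum(w))
  structure(list(estimate = est, se = se, p = 2 * pnorm(-abs(est / se)),
                 n_studies = sum(keep),
                 inputs = data.frame(estimate = b, se = s)),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("IVW fixed-effect meta-analysis of %d input(s)\n", x$n_studies))
  cat(sprintf("  pooled estimate %.4f (SE %.4f), p = %.3g\n",
              x$estimate, x$se, x$p))
  invisible(x)
}

#' Bonferroni significance threshold
#'
#' @param n_tests Number of tests in the family (>= 1).
#' @param alpha Family-wise error rate (default 0.05).
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(522) # 9.58e-05
#' bonferroni_threshold(16)  # 3.13e-03
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  if (!is.numeric(n_tests) || n_tests < 1)
    stop_config("n_tests must be >= 1")
  alpha / n_tests
}

#' Multiple-testing ledger for the phenotype regression battery
#'
#' The battery's test count is phenotypes x prematurity levels x model
#' variants; the ledger records the count and the Bonferroni threshold so a
#' run manifest can report exactly what was corrected for.
#'
#' @param n_phenotypes,n_levels,n_models Battery dimensions (defaults: 29
#'   phenotypes, 3 prematurity levels, 6 model variants = 522 tests).
#' @param alpha Family-wise alpha.
#' @return List with `n_tests` and `threshold`.
#' @export
test_ledger <- function(n_phenotypes = 29, n_levels = 3, n_models = 6,
                        alpha = 0.05) {
  n <- n_phenotypes * n_levels * n_models
  list(n_tests = n, threshold = bonferroni_threshold(n, alpha))
}
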