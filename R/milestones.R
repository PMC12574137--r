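#' Kaplan-Meier curves with a k-group log-rank test
#'
#' Product-limit survival estimates of time to milestone attainment per
#' group, with the k-group log-rank chi-square test (k - 1 degrees of
#' freedom) for a difference between groups.
#'
#' @param times Positive times to attainment (or censoring).
#' @param events 1 = milestone attained, 0 = right-censored.
#' @param groups Group labels (e.g. gestational age categories).
#' @return List of class `km_logrank`: `fit` (a
#'   [survival::survfit] object), `chisq`, `df`, `p`, `n_events`.
#' @export
km_logrank <- function(times, events, groups) {
  if (any(times <= 0, na.rm = TRUE)) stop_data("times must be > 0")
  if (sum(events, na.rm = TRUE) == 0) stop_data("no events")
  groups <- droplevels(factor(groups))
  ev_by_group <- tapply(events, groups, sum)
  if (nlevels(groups) < 2 || any(ev_by_group == 0))
    stop_data("log-rank requires >= 2 groups with >= 1 event each")
  s <- survival::Surv(times, events)
  fit <- survival::survfit(s ~ groups)
  sd_ <- survival::survdiff(s ~ groups)
  df <- length(sd_$n) - 1
  structure(list(fit = fit, chisq = unname(sd_$chisq), df = df,
                 p = pchisq(sd_$chisq, df, lower.tail = FALSE),
                 n_events = sum(events)),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f on %d df, p = %.4g (%d events)\n",
              x$chisq, x$df, x$p, x$n_events))
  invisible(x)
}

#' Cox proportional-hazards model for milestone attainment
#'
#' Partial-likelihood fit (Efron tie handling — ties are common in
#' month-resolution milestone data) of time to attainment on prematurity
#' category dummies plus adjustment covariates, typically proband age, sex,
#' diagnosis, and a prematurity-by-diagnosis interaction. Hazard ratios
#' below 1 indicate slower attainment.
#'
#' @param times,events As in [km_logrank].
#' @param covariates Data frame of covariates; factors are expanded to
#'   dummies by the model.
#' @return Data frame of class `cox_result`: per term, `term`, `estimate`
#'   (log HR), `se`, `hr`, `hr_lo`, `hr_hi`, `p`, `n`, `converged`.
#' @export
cox_milestone_model <- function(times, events, covariates) {
  stopifnot(is.data.frame(covariates))
  if (sum(events, na.rm = TRUE) == 0) stop_data("no events")
  constant <- vapply(covariates, function(v) length(unique(v[!is.na(v)])) < 2,
                     logical(1))
  if (any(constant))
    stop_data("constant covariate(s): ",
              paste(names(covariates)[constant], collapse = ", "))
  dat <- cbind(data.frame(.time = times, .event = events), covariates)
  f <- as.formula(paste("survival::Surv(.time, .event) ~",
                        paste(names(covariates), collapse = " + ")))
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(f, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite", conditionMessage(w)))
        warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  co <- sm$coefficients
  est <- co[, "coef"]; se <- co[, "se(coef)"]; p <- co[, ncol(co)]
  diverged <- warned | abs(est) > 15 | se > 100
  res <- data.frame(term = rownames(co), estimate = est, se = se,
                    hr = exp(est),
                    hr_lo = exp(est - qnorm(0.975) * se),
                    hr_hi = exp(est + qnorm(0.975) * se),
                    p = p, n = fit$n, converged = !diverged,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("cox_result", "data.frame")
  res
}

#' Run the milestone survival battery on a simulated or real cohort
#'
#' For each milestone: Kaplan-Meier curves with a log-rank test across
#' gestational age groups (ledger: 0.05 / number of milestones), and a Cox
#' model adjusted for age at assessment, sex, diagnosis and the
#' prematurity-by-diagnosis interaction (ledger: 0.05 / (6 terms x
#' milestones)).
#'
#' @param cohort Cohort table with `ms_<m>_months` / `ms_<m>_event` columns
#'   (as produced by [simulate_milestones]).
#' @param milestones Milestone names; default: inferred from columns.
#' @param correct_gestation Subtract the gestational shortfall vs 40 weeks
#'   (in months) from milestone ages before analysis. Default `FALSE`.
#' @return List of class `milestone_battery`: per milestone, the
#'   [km_logrank] result and [cox_milestone_model] table, plus the two
#'   Bonferroni ledgers.
#' @export
milestone_battery <- function(cohort, milestones = NULL,
                              correct_gestation = FALSE) {
  if (is.null(milestones)) {
    cols <- grep("^ms_.*_months$", names(cohort), value = TRUE)
    milestones <- sub("^ms_(.*)_months$", "\\1", cols)
  }
  if (!length(milestones)) stop_data("no milestone columns found")
  out <- lapply(milestones, function(m) {
    tt <- cohort[[paste0("ms_", m, "_months")]]
    ev <- cohort[[paste0("ms_", m, "_event")]]
    if (correct_gestation)
      tt <- pmax(tt - (40 - cohort$gestational_weeks) * 12 / 52.18, 0.01)
    covs <- data.frame(
      prematurity_category = cohort$prematurity_category,
      age_at_assessment_years = cohort$age_at_assessment_years,
      sex = cohort$sex, diagnosed = cohort$diagnosed)
    covs$prematurity_category <- droplevels(covs$prematurity_category)
    cox_covs <- covs
    cox_covs$diag_interaction <- NULL
    list(km = km_logrank(tt, ev, cohort$prematurity_category),
         cox = cox_milestone_model(tt, ev, cbind(
           covs, data.frame(diag_x_preterm =
             as.integer(cohort$prematurity_category != "term") *
               cohort$diagnosed))))
  })
  names(out) <- milestones
  n_cox_terms <- sum(vapply(out, function(o)
    sum(grepl("prematurity|diag_x", o$cox$term)), integer(1)))
  structure(list(milestones = out,
                 ledgers = list(
                   logrank = list(n_tests = length(milestones),
                                  threshold = bonferroni_threshold(length(milestones))),
                   cox = list(n_tests = n_cox_terms,
                              threshold = bonferroni_threshold(max(n_cox_terms, 1))))),
            class = "milestone_battery")
}

#' @export
print.milestone_battery <- function(x, ...) {
  cat("Milestone survival battery (", length(x$milestones), " milestones)\n",
      sep = "")
  for (m in names(x$milestones)) {
    cat("\n--", m, "--\n")
    print(x$milestones[[m]]$km)
    cox <- x$milestones[[m]]$cox
    cox$hr <- round(cox$hr, 2); cox$p <- signif(cox$p, 2)
    print(cox[c("term", "hr", "p", "converged")], row.names = FALSE)
  }
  invisible(x)
}
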