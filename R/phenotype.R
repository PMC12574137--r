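PREMATURITY_LEVELS <- c("term", "moderate", "very", "extreme")

#' Classify gestational age into WHO prematurity categories
#'
#' Preterm birth is delivery before 37 completed weeks, subdivided per the
#' WHO definitions: extreme (< 28 weeks), very (28 to < 32 weeks), moderate
#' (32 to < 37 weeks); 37 or more completed weeks is term. Fractional input
#' is floored to completed weeks with a warning.
#'
#' @param gestational_weeks Numeric vector of completed weeks, in `[22, 44]`.
#' @return Factor with levels `term`, `moderate`, `very`, `extreme`.
#' @examples
#' classify_prematurity(c(27, 28, 36, 37))
#' @export
classify_prematurity <- function(gestational_weeks) {
  w <- gestational_weeks
  if (any(!is.finite(w))) stop_data("gestational weeks must be finite")
  if (any(w != floor(w))) {
    warning("fractional gestational weeks floored to completed weeks")
    w <- floor(w)
  }
  if (any(w < 22 | w > 44))
    stop_data("gestational weeks outside [22, 44]: ",
              paste(utils::head(w[w < 22 | w > 44], 5), collapse = ", "))
  cat_ <- ifelse(w >= 37, "term",
          ifelse(w >= 32, "moderate",
          ifelse(w >= 28, "very", "extreme")))
  factor(cat_, levels = PREMATURITY_LEVELS)
}

category_week_range <- function(category) {
  switch(category,
         term     = c(37L, 42L),
         moderate = c(32L, 36L),
         very     = c(28L, 31L),
         extreme  = c(22L, 27L),
         stop_config("unknown prematurity category: ", category))
}

#' Read an LMS growth reference table
#'
#' @param path TSV with columns `sex`, `gestational_weeks`, `L`, `M`, `S`.
#' @return Data frame of class `lms_reference`.
#' @export
read_lms_reference <- function(path) {
  ref <- read_tsv(path)
  as_lms_reference(ref)
}

#' @rdname read_lms_reference
#' @param ref Data frame with the LMS columns.
#' @export
as_lms_reference <- function(ref) {
  need <- c("sex", "gestational_weeks", "L", "M", "S")
  if (!all(need %in% names(ref)))
    stop_data("LMS reference must have columns: ", paste(need, collapse = ", "))
  if (any(ref$M <= 0) || any(ref$S <= 0))
    stop_data("LMS reference requires M > 0 and S > 0")
  if (anyDuplicated(ref[c("sex", "gestational_weeks")]))
    stop_data("duplicate (sex, gestational_weeks) rows in LMS reference")
  class(ref) <- c("lms_reference", "data.frame")
  ref
}

#' Birthweight z-score from an LMS growth reference
#'
#' The LMS method summarises a reference distribution by skewness (L),
#' median (M) and coefficient of variation (S) per sex and gestational week:
#' `z = ((x/M)^L - 1) / (L * S)` for `|L| > 1e-8`, and the limiting form
#' `z = log(x/M) / S` as `L` approaches 0. Lookup is exact on
#' (sex, completed week); no interpolation.
#'
#' @param weight_g Birthweight in grammes (> 0).
#' @param sex Sex codes matching the reference's `sex` column.
#' @param gestational_weeks Completed weeks.
#' @param ref An `lms_reference`.
#' @return Numeric vector of z-scores.
#' @export
birthweight_zscore <- function(weight_g, sex, gestational_weeks, ref) {
  stopifnot(inherits(ref, "lms_reference"))
  if (any(weight_g <= 0, na.rm = TRUE)) stop_data("birthweight must be > 0")
  key <- paste(sex, gestational_weeks)
  refkey <- paste(ref$sex, ref$gestational_weeks)
  idx <- match(key, refkey)
  if (anyNA(idx[!is.na(weight_g)]))
    stop_data("no LMS reference row for: ",
              paste(unique(key[is.na(idx)]), collapse = "; "))
  L <- ref$L[idx]; M <- ref$M[idx]; S <- ref$S[idx]
  ifelse(abs(L) > 1e-8,
         ((weight_g / M)^L - 1) / (L * S),
         log(weight_g / M) / S)
}

#' Remove birthweight outliers relative to the growth reference
#'
#' Drops probands whose birthweight lies more than `threshold` standard
#' deviations from the reference mean for their gestational duration and
#' sex; rows with missing birthweight are kept. The number removed is
#' reported via `message()`.
#'
#' @param cohort A cohort table with `birthweight_g`, `sex`,
#'   `gestational_weeks` columns.
#' @param ref An `lms_reference`.
#' @param threshold Absolute z-score cutoff (default 5).
#' @return The filtered cohort table.
#' @export
filter_birthweight_outliers <- function(cohort, ref, threshold = 5) {
  z <- birthweight_zscore(cohort$birthweight_g, cohort$sex,
                          cohort$gestational_weeks, ref)
  drop <- !is.na(z) & abs(z) > threshold
  message(sum(drop), " proband(s) removed as birthweight outliers (|z| > ",
          threshold, ")")
  cohort[!drop, , drop = FALSE]
}

#' Summarise a cohort table
#'
#' Per-category proband counts and percentages, and diagnostic yield overall
#' and within each gestational age group — the descriptive statistics
#' typically reported for clinical-sequencing cohorts.
#'
#' @param cohort A cohort table with `prematurity_category` and `diagnosed`.
#' @return A list of class `cohort_summary` with elements `n`,
#'   `category` (count, pct per category) and `diagnosis` (count, pct of
#'   diagnosed overall and per category).
#' @export
cohort_summary <- function(cohort) {
  stopifnot(all(c("prematurity_category", "diagnosed") %in% names(cohort)))
  cat_ <- factor(cohort$prematurity_category, levels = PREMATURITY_LEVELS)
  n <- nrow(cohort)
  counts <- table(cat_)
  category <- data.frame(category = names(counts),
                         n = as.integer(counts),
                         pct = 100 * as.integer(counts) / n)
  diag_n <- sum(cohort$diagnosed == 1)
  by_cat <- vapply(PREMATURITY_LEVELS, function(cc) {
    sel <- cat_ == cc
    c(n = sum(cohort$diagnosed[sel] == 1),
      pct = if (any(sel)) 100 * mean(cohort$diagnosed[sel] == 1) else NA_real_)
  }, numeric(2))
  diagnosis <- data.frame(group = c("all", PREMATURITY_LEVELS),
                          n_diagnosed = c(diag_n, by_cat["n", ]),
                          pct = c(100 * diag_n / n, by_cat["pct", ]))
  structure(list(n = n, category = category, diagnosis = diagnosis),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort of", x$n, "probands\n\nGestational age group:\n")
  print(transform(x$category, pct = round(pct, 1)), row.names = FALSE)
  cat("\nDiagnosed:\n")
  print(transform(x$diagnosis, pct = round(pct, 1)), row.names = FALSE)
  invisible(x)
}
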