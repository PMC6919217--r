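#' Per-day at-risk counts
#'
#' An admission is "at risk" on integer day `d` when its ICU length of stay
#' is at least `d` days: it reached that duration of ICU stay, so it belongs
#' to the denominator of the day-`d` conditional survival proportion. Day 0
#' therefore includes every admission; a stay of 1.9 days is at risk on days
#' 0 and 1 but not day 2.
#'
#' @param cohort A filtered cohort tibble (see [apply_inclusion_criteria()]).
#' @param max_day Optional last day to enumerate; by default enumeration runs
#'   until the at-risk count reaches zero.
#' @return A tibble with columns `day` and `n_at_risk`, non-increasing in
#'   `day`, starting at day 0.
#' @export
at_risk_counts <- function(cohort, max_day = NULL) {
  los <- cohort$icu_los_days
  last <- if (is.null(max_day)) {
    if (nrow(cohort) == 0) 0L else as.integer(floor(max(los))) + 1L
  } else {
    as.integer(max_day)
  }
  days <- 0:last
  tibble::tibble(
    day = days,
    n_at_risk = vapply(days, function(d) sum(los >= d), integer(1))
  )
}

#' Estimate the conditional survival curve
#'
#' The day-`d` conditional survival is the proportion of admissions
#' surviving to hospital discharge among those whose ICU stay lasted at
#' least `d` days. It is computed for each integer day from zero upward,
#' stopping at the first day on which fewer than `min_at_risk` admissions
#' reached that length of stay (the default of 50 bounds the width of the
#' confidence intervals). Because every admission's discharge status is
#' known, no censoring occurs and simple binomial methods apply: each point
#' gets an Agresti-Coull interval at level `conf`.
#'
#' The day-0 value equals the cohort's overall survival-to-discharge
#' proportion.
#'
#' @param cohort A filtered cohort tibble.
#' @param min_at_risk Minimum at-risk count for a day to be reported
#'   (default 50).
#' @param conf Confidence level for the intervals (default 0.95).
#' @param label Curve label; defaults to the cohort's `label` attribute.
#' @return A `cs_curve` tibble with columns `day`, `n_at_risk`,
#'   `n_survivors`, `cs`, `ci_lower`, `ci_upper`, and attributes
#'   `min_at_risk`, `conf`, `label`.
#' @export
#' @examples
#' cohort <- as_cohort(data.frame(
#'   patient_id = paste0("p", 1:4), admission_id = paste0("a", 1:4),
#'   age_years = c(40, 55, 70, 80), icu_los_days = c(1, 2, 3, 5),
#'   survived_to_discharge = c(1, 1, 0, 1)
#' ))
#' estimate_conditional_survival(cohort, min_at_risk = 1)
estimate_conditional_survival <- function(cohort, min_at_risk = 50, conf = 0.95,
                                          label = NULL) {
  if (min_at_risk < 1) {
    rlang::abort("min_at_risk must be >= 1", class = "icusurv_parameter_error")
  }
  label <- label %||% attr(cohort, "label") %||% "cohort"
  if (nrow(cohort) < min_at_risk) {
    rlang::abort(paste0(
      "Cohort has ", nrow(cohort), " admissions, fewer than min_at_risk = ",
      min_at_risk, "; lower the threshold to obtain a curve"),
      class = "icusurv_empty_curve_error")
  }
  risk <- at_risk_counts(cohort)
  keep <- risk$n_at_risk >= min_at_risk
  # truncate at the FIRST day under threshold (counts are non-increasing,
  # so this is just the leading run)
  last_day <- which(!keep)[1]
  if (!is.na(last_day)) keep[last_day:length(keep)] <- FALSE
  risk <- risk[keep, , drop = FALSE]

  los <- cohort$icu_los_days
  surv <- cohort$survived_to_discharge
  n_survivors <- vapply(risk$day, function(d) sum(surv[los >= d]), integer(1))
  ci <- agresti_coull(n_survivors, risk$n_at_risk, conf)

  new_cs_curve(
    tibble::tibble(
      day = risk$day,
      n_at_risk = risk$n_at_risk,
      n_survivors = n_survivors,
      cs = n_survivors / risk$n_at_risk,
      ci_lower = ci$lower,
      ci_upper = ci$upper
    ),
    min_at_risk = min_at_risk, conf = conf, label = label
  )
}

new_cs_curve <- function(data, min_at_risk, conf, label) {
  attr(data, "min_at_risk") <- min_at_risk
  attr(data, "conf") <- conf
  attr(data, "label") <- label
  class(data) <- c("cs_curve", class(data))
  data
}

empty_cs_curve <- function(min_at_risk, conf, label) {
  new_cs_curve(
    tibble::tibble(day = integer(), n_at_risk = integer(),
                   n_survivors = integer(), cs = double(),
                   ci_lower = double(), ci_upper = double()),
    min_at_risk = min_at_risk, conf = conf, label = label
  )
}

#' Split a cohort at an age cutoff
#'
#' Partitions a cohort into the stratum younger than `cutoff` and the
#' stratum aged `cutoff` or older (the boundary age belongs to the older
#' stratum). The default cutoff of 75 years is the conventional threshold
#' for "elderly" ICU patients.
#'
#' @param cohort A filtered cohort tibble.
#' @param cutoff Age cutoff in years (default 75).
#' @return A list with cohort tibbles `young` (age < cutoff) and `old`
#'   (age >= cutoff); every record lands in exactly one stratum.
#' @export
stratify_by_age <- function(cohort, cutoff = 75) {
  label <- attr(cohort, "label") %||% "cohort"
  young <- cohort[cohort$age_years < cutoff, , drop = FALSE]
  old <- cohort[cohort$age_years >= cutoff, , drop = FALSE]
  attr(young, "label") <- paste0(label, " (age < ", cutoff, ")")
  attr(old, "label") <- paste0(label, " (age >= ", cutoff, ")")
  list(young = young, old = old)
}

#' @export
print.cs_curve <- function(x, ...) {
  cat("Conditional survival curve: ", attr(x, "label"),
      " (min at risk ", attr(x, "min_at_risk"),
      ", conf ", attr(x, "conf"), ")\n", sep = "")
  NextMethod()
}
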