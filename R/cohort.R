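#' Read an admission-level cohort table
#'
#' Reads a CSV with one row per ICU admission and returns a validated cohort
#' tibble. Each record carries the patient and admission identifiers, the
#' admission order (1 = the patient's first ICU admission), age at ICU
#' admission in years, sex, ICU length of stay in (possibly fractional) days,
#' and vital status at *hospital* discharge.
#'
#' Vital status values `1/0`, `true/false`, `t/f`, `yes/no` (any case) are
#' recognised; anything else, including an empty cell, becomes `NA`
#' ("missing"). Missingness is resolved later by
#' [apply_inclusion_criteria()], never silently at read time.
#'
#' @param path Path to a CSV file (RFC-4180, UTF-8, header row required).
#' @param column_map Optional named character vector mapping cohort fields to
#'   source column names, e.g. `c(age_years = "AGE", icu_los_days = "LOS")`.
#'   Unmapped fields are looked up under their default names. The
#'   `admission_order` and `sex` columns are optional in the source file.
#' @param label Cohort label carried through the analysis (defaults to the
#'   file name).
#' @return A tibble with columns `patient_id`, `admission_id`,
#'   `admission_order`, `age_years`, `sex`, `icu_los_days`,
#'   `survived_to_discharge`, and a `label` attribute.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "patient_id,admission_id,age_years,icu_los_days,survived_to_discharge",
#'   "p1,a1,67,2.5,1",
#'   "p2,a2,45,0.9,0"
#' ), path)
#' read_cohort(path)
read_cohort <- function(path, column_map = NULL, label = basename(path)) {
  if (!file.exists(path)) {
    rlang::abort(paste0("Cohort file not found: ", path), class = "icusurv_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  as_cohort(raw, column_map = column_map, label = label)
}

#' Coerce a data frame to a validated cohort tibble
#'
#' @param data A data frame of admission records.
#' @inheritParams read_cohort
#' @return A cohort tibble (see [read_cohort()]).
#' @export
as_cohort <- function(data, column_map = NULL, label = "cohort") {
  fields <- c("patient_id", "admission_id", "admission_order", "age_years",
              "sex", "icu_los_days", "survived_to_discharge")
  map <- stats::setNames(fields, fields)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), fields)
    if (length(bad) > 0) {
      rlang::abort(paste0("Unknown cohort field(s) in column_map: ",
                          paste(bad, collapse = ", ")), class = "icusurv_schema_error")
    }
    map[names(column_map)] <- unname(column_map)
  }
  optional <- c("admission_order", "sex")
  required <- setdiff(fields, optional)
  missing_cols <- map[required][!map[required] %in% names(data)]
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("Missing required column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "icusurv_schema_error")
  }

  get_col <- function(field) {
    src <- map[[field]]
    if (src %in% names(data)) data[[src]] else rep(NA_character_, nrow(data))
  }

  cohort <- tibble::tibble(
    patient_id = as.character(get_col("patient_id")),
    admission_id = as.character(get_col("admission_id")),
    admission_order = suppressWarnings(as.integer(get_col("admission_order"))),
    age_years = suppressWarnings(as.numeric(get_col("age_years"))),
    sex = parse_sex(get_col("sex")),
    icu_los_days = suppressWarnings(as.numeric(get_col("icu_los_days"))),
    survived_to_discharge = parse_vital_status(get_col("survived_to_discharge"))
  )
  validate_cohort(cohort)
  attr(cohort, "label") <- label
  cohort
}

parse_vital_status <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) x <- as.character(x)
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "t", "yes", "y")] <- TRUE
  out[x %in% c("0", "false", "f", "no", "n")] <- FALSE
  out
}

parse_sex <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("male", "m")] <- "male"
  out[x %in% c("female", "f")] <- "female"
  out[!is.na(x) & x != "" & is.na(out)] <- "other/unknown"
  out
}

validate_cohort <- function(cohort) {
  bad_los <- which(!is.na(cohort$icu_los_days) & cohort$icu_los_days < 0)
  if (length(bad_los) > 0) {
    rlang::abort(paste0("Negative ICU length of stay at row(s): ",
                        paste(utils::head(bad_los, 5), collapse = ", ")),
                 class = "icusurv_validation_error")
  }
  bad_age <- which(!is.na(cohort$age_years) & cohort$age_years < 0)
  if (length(bad_age) > 0) {
    rlang::abort(paste0("Negative age at row(s): ",
                        paste(utils::head(bad_age, 5), collapse = ", ")),
                 class = "icusurv_validation_error")
  }
  key <- paste(cohort$patient_id, cohort$admission_id, sep = "\r")
  if (anyDuplicated(key) > 0) {
    rlang::abort("Duplicate (patient_id, admission_id) pairs in cohort",
                 class = "icusurv_validation_error")
  }
  invisible(cohort)
}

#' Write a cohort tibble back to CSV
#'
#' Emits the cohort in the same dialect [read_cohort()] accepts, so a
#' filtered cohort can be re-read and re-analysed (`TRUE`/`FALSE` status is
#' written as `1`/`0`; missing values as empty cells).
#'
#' @param cohort A cohort tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  out$survived_to_discharge <- ifelse(is.na(out$survived_to_discharge), NA_integer_,
                                      as.integer(out$survived_to_discharge))
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Apply the cohort inclusion criteria with flow-chart accounting
#'
#' Filters an admission table to the analysis population: adults (age >= 18
#' years at ICU admission), first-ever ICU admission per patient, and a
#' recorded vital status at hospital discharge with non-missing age and
#' length of stay. Criteria are applied sequentially (age, then index
#' admission, then missing data), so every excluded record is attributed to
#' exactly the first criterion it fails and the counts sum to the raw total.
#'
#' When `admission_order` is present, the index admission is the record with
#' `admission_order == 1`; records whose order is `NA` cannot be confirmed as
#' index admissions and are excluded at the missing-data step. When the
#' column is absent (or entirely `NA`) the record with the lexicographically
#' smallest `admission_id` per patient is kept instead.
#'
#' The reported missing-data percentage uses the included-plus-missing
#' denominator, `100 * n_excluded_missing / (n_included + n_excluded_missing)`,
#' rounded to one decimal — the convention under which 524 exclusions against
#' 11,648 included admissions reads as 4.3%.
#'
#' @param raw A cohort tibble from [read_cohort()] or [as_cohort()].
#' @return A list with elements `cohort` (the filtered tibble) and
#'   `exclusions` (a one-row `exclusion_report` tibble with columns `n_raw`,
#'   `n_excluded_age`, `n_excluded_not_index`, `n_excluded_missing`,
#'   `n_included`, `pct_excluded_missing`).
#' @export
apply_inclusion_criteria <- function(raw) {
  if (nrow(raw) == 0) {
    rlang::abort("Cannot apply inclusion criteria to an empty cohort",
                 class = "icusurv_empty_cohort_error")
  }
  n_raw <- nrow(raw)

  # (1) adults only; unknown ages fall through to the missing-data step
  fail_age <- !is.na(raw$age_years) & raw$age_years < 18
  step1 <- raw[!fail_age, , drop = FALSE]

  # (2) index (first-ever ICU) admission per patient
  have_order <- "admission_order" %in% names(step1) && any(!is.na(step1$admission_order))
  if (have_order) {
    fail_index <- !is.na(step1$admission_order) & step1$admission_order != 1L
  } else {
    first_id <- step1 |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::mutate(.is_index = .data$admission_id == min(.data$admission_id)) |>
      dplyr::ungroup()
    fail_index <- !first_id$.is_index
  }
  step2 <- step1[!fail_index, , drop = FALSE]

  # (3) complete data: status, age, LOS (and admission order when in use)
  fail_missing <- is.na(step2$survived_to_discharge) | is.na(step2$age_years) |
    is.na(step2$icu_los_days)
  if (have_order) fail_missing <- fail_missing | is.na(step2$admission_order)
  included <- step2[!fail_missing, , drop = FALSE]

  n_missing <- sum(fail_missing)
  report <- tibble::tibble(
    n_raw = n_raw,
    n_excluded_age = sum(fail_age),
    n_excluded_not_index = sum(fail_index),
    n_excluded_missing = n_missing,
    n_included = nrow(included),
    pct_excluded_missing = round(100 * n_missing / (nrow(included) + n_missing), 1)
  )
  class(report) <- c("exclusion_report", class(report))
  attr(included, "label") <- attr(raw, "label")
  list(cohort = included, exclusions = report)
}

#' Descriptive summary of a filtered cohort
#'
#' Median and interquartile range (25th/75th percentiles, linear
#' interpolation) of age and ICU length of stay, the percentage male, the
#' percentage surviving to hospital discharge, and the cohort size.
#'
#' @param cohort A filtered cohort tibble (no missing age, LOS, or status).
#' @param label Optional label; defaults to the cohort's `label` attribute.
#' @return A one-row tibble: `n`, `median_age`, `iqr_age_lower`,
#'   `iqr_age_upper`, `pct_male`, `median_los`, `iqr_los_lower`,
#'   `iqr_los_upper`, `pct_survived`, `label`.
#' @export
summarize_cohort <- function(cohort, label = NULL) {
  if (nrow(cohort) == 0) {
    rlang::abort("Cannot summarize an empty cohort",
                 class = "icusurv_empty_cohort_error")
  }
  label <- label %||% attr(cohort, "label") %||% "cohort"
  q_age <- stats::quantile(cohort$age_years, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  q_los <- stats::quantile(cohort$icu_los_days, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  tibble::tibble(
    n = nrow(cohort),
    median_age = q_age[2], iqr_age_lower = q_age[1], iqr_age_upper = q_age[3],
    pct_male = 100 * mean(cohort$sex == "male", na.rm = TRUE),
    median_los = q_los[2], iqr_los_lower = q_los[1], iqr_los_upper = q_los[3],
    pct_survived = 100 * mean(cohort$survived_to_discharge),
    label = label
  )
}
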