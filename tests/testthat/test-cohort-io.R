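test_that("read_cohort parses a well-formed CSV and propagates missing status", {
  df <- data.frame(
    patient_id = c("p1", "p2", "p3"),
    admission_id = c("a1", "a2", "a3"),
    admission_order = c(1, 1, 1),
    age_years = c(67, 45, 80),
    sex = c("male", "female", "M"),
    icu_los_days = c(2.5, 0.9, 10),
    survived_to_discharge = c("1", "0", "")
  )
  cohort <- read_cohort(write_temp_csv(df))
  expect_equal(nrow(cohort), 3)
  expect_equal(cohort$icu_los_days, c(2.5, 0.9, 10))
  expect_equal(cohort$survived_to_discharge, c(TRUE, FALSE, NA))
  expect_equal(cohort$sex, c("male", "female", "male"))
})

test_that("read_cohort honours a column map and names missing columns", {
  df <- data.frame(PTID = "p1", ADMID = "a1", AGE = 60, LOS = 3, DIED = 0)
  path <- write_temp_csv(df)
  cohort <- read_cohort(path, column_map = c(
    patient_id = "PTID", admission_id = "ADMID", age_years = "AGE",
    icu_los_days = "LOS", survived_to_discharge = "DIED"
  ))
  expect_equal(cohort$age_years, 60)
  expect_error(
    read_cohort(path, column_map = c(age_years = "WRONG")),
    "WRONG", class = "icusurv_schema_error"
  )
})

test_that("negative LOS or age is rejected with the offending row", {
  df <- make_cohort(los = c(1, -1, 2))
  expect_error(as_cohort(df), "row.*2", class = "icusurv_validation_error")
  df2 <- make_cohort(age = c(50, 60, -3))
  expect_error(as_cohort(df2), "row.*3", class = "icusurv_validation_error")
  expect_error(as_cohort(make_cohort(n = 2) |>
                           dplyr::mutate(patient_id = "p1", admission_id = "a1")),
               "Duplicate", class = "icusurv_validation_error")
})

test_that("cohort CSV round-trip preserves every field", {
  cohort <- generate_cohort(synthetic_params(n = 50, seed = 3))
  cohort$survived_to_discharge[7] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  for (col in names(cohort)) {
    expect_equal(back[[col]], cohort[[col]], info = col)
  }
})

test_that("inclusion criteria: age boundary at exactly 18, sequential accounting", {
  raw <- make_cohort(age = c(17.9, 18.0, 80))
  res <- apply_inclusion_criteria(raw)
  expect_equal(res$exclusions$n_excluded_age, 1)
  expect_equal(res$exclusions$n_included, 2)
  expect_true(all(res$cohort$age_years >= 18))
})

test_that("only the index admission is retained", {
  raw <- make_cohort(n = 3, order = c(1L, 2L, 3L))
  raw$patient_id <- "p1"
  res <- apply_inclusion_criteria(raw)
  expect_equal(res$cohort$admission_order, 1L)
  expect_equal(res$exclusions$n_excluded_not_index, 2)

  # fallback without admission_order: smallest admission_id per patient
  raw2 <- make_cohort(n = 4)
  raw2$admission_order <- NA_integer_
  raw2$patient_id <- c("p1", "p1", "p2", "p2")
  raw2$admission_id <- c("a2", "a1", "b9", "b10")
  res2 <- apply_inclusion_criteria(raw2)
  expect_setequal(res2$cohort$admission_id, c("a1", "b10"))  # lexicographic
})

test_that("missing-data exclusions use the included-plus-missing denominator", {
  # 12,172 eligible admissions of which 524 lack vital status
  status <- c(rep(TRUE, 12172 - 524), rep(NA, 524))
  raw <- make_cohort(survived = status)
  res <- apply_inclusion_criteria(raw)
  expect_equal(res$exclusions$n_included, 11648)
  expect_equal(res$exclusions$n_excluded_missing, 524)
  expect_equal(res$exclusions$pct_excluded_missing, 4.3)
})

test_that("exclusion counts always sum to n_raw and filtering is idempotent", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    raw <- make_cohort(
      n = n,
      age = sample(c(10, 17.9, 18, 50, NA), n, replace = TRUE),
      order = sample(c(1L, 1L, 2L), n, replace = TRUE),
      survived = sample(c(TRUE, FALSE, NA), n, replace = TRUE),
      los = sample(c(0.5, 2, NA), n, replace = TRUE)
    )
    res <- apply_inclusion_criteria(raw)
    ex <- res$exclusions
    expect_equal(ex$n_raw, ex$n_included + ex$n_excluded_age +
                   ex$n_excluded_not_index + ex$n_excluded_missing)
    if (nrow(res$cohort) > 0) {
      twice <- apply_inclusion_criteria(res$cohort)
      expect_equal(twice$cohort, res$cohort, ignore_attr = TRUE)
      expect_equal(twice$exclusions$n_included, ex$n_included)
    }
  }
  expect_error(apply_inclusion_criteria(make_cohort(n = 1)[0, ]),
               class = "icusurv_empty_cohort_error")
})

test_that("cohort summary gives interpolated quartiles and percentages", {
  cohort <- as_cohort(make_cohort(age = c(50, 64, 74), los = c(1, 2, 3)))
  s <- summarize_cohort(cohort)
  expect_equal(s$median_age, 64)
  expect_equal(s$iqr_age_lower, 57)
  expect_equal(s$iqr_age_upper, 69)
  expect_equal(s$pct_male, 100)

  big <- make_cohort(survived = c(rep(TRUE, 815), rep(FALSE, 185)))
  expect_equal(summarize_cohort(big)$pct_survived, 81.5)
})
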