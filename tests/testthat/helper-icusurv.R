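# Shared builders and independent oracles for the test suite.

# Quick cohort builder: valid defaults, override any field.
make_cohort <- function(n = NULL, los = 1, survived = TRUE, age = 50,
                        order = 1L, sex = "male") {
  n <- n %||% max(length(los), length(survived), length(age), length(order))
  tibble::tibble(
    patient_id = paste0("p", seq_len(n)),
    admission_id = paste0("a", seq_len(n)),
    admission_order = rep_len(as.integer(order), n),
    age_years = rep_len(age, n),
    sex = rep_len(sex, n),
    icu_los_days = rep_len(los, n),
    survived_to_discharge = rep_len(survived, n)
  )
}

# Independent brute-force conditional-survival oracle: per-day filtering and
# tallying, no shared code with the estimator.
brute_force_cs <- function(los, survived, min_at_risk = 1) {
  rows <- list()
  d <- 0
  repeat {
    at_risk <- which(los >= d)
    if (length(at_risk) < min_at_risk) break
    rows[[length(rows) + 1]] <- data.frame(
      day = d,
      n_at_risk = length(at_risk),
      n_survivors = sum(survived[at_risk]),
      cs = sum(survived[at_risk]) / length(at_risk)
    )
    d <- d + 1
  }
  do.call(rbind, rows)
}

# Write a cohort data frame to a temp CSV and return the path.
write_temp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  readr::write_csv(df, path, na = "")
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
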