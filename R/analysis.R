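#' Run the full conditional-survival analysis on a cohort
#'
#' Orchestrates the per-database pipeline: applies the inclusion criteria
#' once, summarises the filtered cohort, estimates the overall
#' conditional-survival curve, stratifies at the age cutoff, estimates each
#' stratum's curve (each independently truncated at `min_at_risk`, so the
#' older stratum typically truncates earlier), smooths every non-degenerate
#' curve, and bundles everything with an echo of the parameters used. The
#' whole computation is deterministic.
#'
#' A stratum smaller than `min_at_risk` yields an empty curve with a
#' warning; the other results are unaffected.
#'
#' @param raw A cohort tibble (unfiltered is fine; criteria are applied
#'   here).
#' @param min_at_risk Truncation threshold for every curve (default 50).
#' @param conf Confidence level (default 0.95).
#' @param age_cutoff Age stratification cutoff in years (default 75).
#' @param span LOESS span for presentation smoothing (default 0.5).
#' @param loess_degree LOESS polynomial degree (default 2).
#' @param label Analysis label; defaults to the cohort's `label` attribute.
#' @return An `icusurv_analysis` object: a list with `summaries` (tibble,
#'   one row per stratum incl. overall), `curves` and `smooths` (named lists
#'   with elements `overall`, `young`, `old`), `exclusions`, `cohort` (the
#'   filtered table), and `config` (the parameters used).
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_params(n = 2000, seed = 7))
#' fit <- run_analysis(cohort, min_at_risk = 25)
#' glance(fit)
run_analysis <- function(raw, min_at_risk = 50, conf = 0.95, age_cutoff = 75,
                         span = 0.5, loess_degree = 2, label = NULL) {
  label <- label %||% attr(raw, "label") %||% "cohort"
  filtered <- apply_inclusion_criteria(raw)
  cohort <- filtered$cohort
  attr(cohort, "label") <- label

  strata <- stratify_by_age(cohort, cutoff = age_cutoff)
  groups <- list(overall = cohort, young = strata$young, old = strata$old)

  summaries <- purrr::imap(groups, function(g, nm) {
    if (nrow(g) == 0) {
      tibble::tibble(n = 0L, median_age = NA_real_, iqr_age_lower = NA_real_,
                     iqr_age_upper = NA_real_, pct_male = NA_real_,
                     median_los = NA_real_, iqr_los_lower = NA_real_,
                     iqr_los_upper = NA_real_, pct_survived = NA_real_,
                     label = paste0(label, " (", nm, ")"))
    } else {
      summarize_cohort(g, label = attr(g, "label") %||% paste0(label, " (", nm, ")"))
    }
  }) |>
    dplyr::bind_rows(.id = "stratum")

  curves <- purrr::map(groups, function(g) {
    if (nrow(g) < min_at_risk) {
      rlang::warn(paste0("Stratum '", attr(g, "label") %||% label, "' has ",
                         nrow(g), " admissions (< min_at_risk = ", min_at_risk,
                         "); its curve is empty"))
      empty_cs_curve(min_at_risk, conf, attr(g, "label") %||% label)
    } else {
      estimate_conditional_survival(g, min_at_risk = min_at_risk, conf = conf)
    }
  })

  smooths <- purrr::map(curves, function(cv) {
    if (nrow(cv) == 0) return(NULL)
    smooth_curve(cv, span = span, degree = loess_degree)
  })

  structure(
    list(
      summaries = summaries,
      curves = curves,
      smooths = smooths,
      exclusions = filtered$exclusions,
      cohort = cohort,
      config = list(min_at_risk = min_at_risk, conf = conf,
                    age_cutoff = age_cutoff, span = span,
                    loess_degree = loess_degree, label = label)
    ),
    class = "icusurv_analysis"
  )
}

#' Compare the age strata of an analysis day by day
#'
#' Inner-joins the young and old stratum curves on the days present in
#' both (the older stratum usually truncates earlier, so the comparison
#' covers its range) and reports the survival difference, young minus old.
#'
#' @param result An `icusurv_analysis` object.
#' @return A tibble with columns `day`, `cs_young`, `cs_old`, `difference`.
#'   Empty, with a warning, when either stratum curve is empty.
#' @export
compare_strata <- function(result) {
  stopifnot(inherits(result, "icusurv_analysis"))
  young <- result$curves$young
  old <- result$curves$old
  if (nrow(young) == 0 || nrow(old) == 0) {
    rlang::warn("One or both age-stratum curves are empty; nothing to compare")
    return(tibble::tibble(day = integer(), cs_young = double(),
                          cs_old = double(), difference = double()))
  }
  dplyr::inner_join(
    dplyr::select(tibble::as_tibble(young), "day", cs_young = "cs"),
    dplyr::select(tibble::as_tibble(old), "day", cs_old = "cs"),
    by = "day"
  ) |>
    dplyr::mutate(difference = .data$cs_young - .data$cs_old)
}

#' @export
print.icusurv_analysis <- function(x, ...) {
  cat("Conditional survival analysis:", x$config$label, "\n")
  cat("  included admissions:", x$exclusions$n_included,
      "of", x$exclusions$n_raw, "\n")
  for (nm in names(x$curves)) {
    cv <- x$curves[[nm]]
    if (nrow(cv) == 0) {
      cat("  ", nm, ": empty curve\n", sep = "")
    } else {
      cat("  ", nm, ": days 0-", max(cv$day),
          ", day-0 survival ", sprintf("%.1f%%", 100 * cv$cs[1]), "\n", sep = "")
    }
  }
  invisible(x)
}

#' Tidy the curves of an analysis into one tibble
#'
#' @param x An `icusurv_analysis` object.
#' @param ... Unused.
#' @return A tibble of all per-day estimates with a `stratum` column
#'   (`overall`, `young`, `old`).
#' @method tidy icusurv_analysis
#' @export
tidy.icusurv_analysis <- function(x, ...) {
  purrr::map(x$curves, tibble::as_tibble) |>
    dplyr::bind_rows(.id = "stratum")
}

#' One-row summary of an analysis
#'
#' @param x An `icusurv_analysis` object.
#' @param ... Unused.
#' @return A one-row tibble: included/excluded counts, day-0 survival, the
#'   last reported day of each curve, and the settings used.
#' @method glance icusurv_analysis
#' @export
glance.icusurv_analysis <- function(x, ...) {
  last_day <- function(cv) if (nrow(cv) == 0) NA_integer_ else max(cv$day)
  tibble::tibble(
    n_raw = x$exclusions$n_raw,
    n_included = x$exclusions$n_included,
    pct_excluded_missing = x$exclusions$pct_excluded_missing,
    day0_survival = if (nrow(x$curves$overall) > 0) x$curves$overall$cs[1] else NA_real_,
    last_day_overall = last_day(x$curves$overall),
    last_day_young = last_day(x$curves$young),
    last_day_old = last_day(x$curves$old),
    min_at_risk = x$config$min_at_risk,
    conf = x$config$conf,
    age_cutoff = x$config$age_cutoff
  )
}

#' @rdname tidy.icusurv_analysis
#' @method tidy cs_curve
#' @export
tidy.cs_curve <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$label <- attr(x, "label") %||% NA_character_
  out
}

#' @rdname glance.icusurv_analysis
#' @method glance cs_curve
#' @export
glance.cs_curve <- function(x, ...) {
  tibble::tibble(
    n_days = nrow(x),
    day0_cs = if (nrow(x) > 0) x$cs[1] else NA_real_,
    last_day = if (nrow(x) > 0) max(x$day) else NA_integer_,
    min_at_risk = attr(x, "min_at_risk"),
    conf = attr(x, "conf"),
    label = attr(x, "label") %||% NA_character_
  )
}
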