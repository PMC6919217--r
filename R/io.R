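#' Export a conditional survival curve as CSV
#'
#' Columns `day`, `n_at_risk`, `n_survivors`, `cs`, `ci_lower`, `ci_upper`,
#' `label`; proportions are written at 6 decimals.
#'
#' @param curve A `cs_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  out <- tibble::as_tibble(curve)
  out$cs <- round(out$cs, 6)
  out$ci_lower <- round(out$ci_lower, 6)
  out$ci_upper <- round(out$ci_upper, 6)
  out$label <- attr(curve, "label") %||% NA_character_
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Export a smoothed curve as CSV with a JSON sidecar
#'
#' The CSV carries `day`, `cs_raw`, `cs_smooth` and the smoothed confidence
#' bounds; the sidecar (`<path>.json`) records the span, degree, family and
#' iteration count, so no smoothing setting is ever implicit in an artifact.
#'
#' @param smooth A `smooth_curve` from [smooth_curve()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_smooth_csv <- function(smooth, path) {
  readr::write_csv(tibble::as_tibble(smooth), path, progress = FALSE)
  meta <- list(span = attr(smooth, "span"), degree = attr(smooth, "degree"),
               family = attr(smooth, "family"),
               iterations = attr(smooth, "iterations"),
               smoothed = attr(smooth, "smoothed") %||% TRUE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Serialize a full analysis to a directory
#'
#' Writes `summaries.json`, `exclusions.json`, `config_echo.json`, the raw
#' per-day estimates under `curves/*.csv`, the smoothed presentation curves
#' under `smooth/*.csv` (with JSON sidecars), and the filtered cohort as
#' `cohort_filtered.csv`. `config_echo.json` is sufficient to re-run the
#' identical analysis.
#'
#' @param result An `icusurv_analysis`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(result, dir) {
  stopifnot(inherits(result, "icusurv_analysis"))
  dir.create(file.path(dir, "curves"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "smooth"), recursive = TRUE, showWarnings = FALSE)

  jsonlite::write_json(result$summaries, file.path(dir, "summaries.json"),
                       dataframe = "rows", pretty = TRUE, digits = NA, na = "null")
  jsonlite::write_json(as.list(tibble::as_tibble(result$exclusions)[1, ]),
                       file.path(dir, "exclusions.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(result$config, file.path(dir, "config_echo.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  for (nm in names(result$curves)) {
    if (nrow(result$curves[[nm]]) > 0) {
      write_curve_csv(result$curves[[nm]], file.path(dir, "curves", paste0(nm, ".csv")))
    }
    if (!is.null(result$smooths[[nm]])) {
      write_smooth_csv(result$smooths[[nm]], file.path(dir, "smooth", paste0(nm, ".csv")))
    }
  }
  write_cohort(result$cohort, file.path(dir, "cohort_filtered.csv"))
  invisible(dir)
}
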