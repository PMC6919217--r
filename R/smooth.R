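#' Locally weighted polynomial smoothing (LOESS)
#'
#' A single-pass locally estimated scatterplot smoother. For each target
#' point the `q = ceiling(span * N)` nearest points (by distance on `x`) are
#' selected, weighted by the tricube kernel
#' `w = (1 - (dist / dist_max)^3)^3` with `dist_max` the largest distance in
#' the neighbourhood, and a weighted least-squares polynomial of the given
#' degree is fitted; the smoothed value is the polynomial evaluated at the
#' target. No robustness (bisquare) reweighting iterations are performed —
#' this is the gaussian-family fit, and the choice is recorded in the
#' result's metadata.
#'
#' Distance ties at the neighbourhood boundary are broken toward the lower
#' `x` first; since the tricube weight at `dist = dist_max` is zero, the tie
#' policy cannot change the fit.
#'
#' A polynomial of degree at most `degree` is reproduced exactly.
#'
#' @param x Strictly increasing abscissae (days).
#' @param y Observed values.
#' @param span Fraction of the data in each local neighbourhood, in (0, 1]
#'   (default 0.5).
#' @param degree Local polynomial degree, 0, 1 or 2 (default 2).
#' @return A `smooth_curve` tibble with columns `x`, `y_raw`, `y_smooth` and
#'   attributes `span`, `degree`, `family` ("gaussian"), `iterations` (0).
#' @export
#' @examples
#' x <- 0:19
#' loess_fit(x, 3 + 2 * x)  # reproduced exactly
loess_fit <- function(x, y, span = 0.5, degree = 2) {
  n <- length(x)
  if (length(y) != n) {
    rlang::abort("x and y must have the same length", class = "icusurv_parameter_error")
  }
  if (!degree %in% 0:2) {
    rlang::abort("degree must be 0, 1 or 2", class = "icusurv_parameter_error")
  }
  if (length(span) != 1 || !is.finite(span) || span <= 0 || span > 1) {
    rlang::abort("span must be in (0, 1]", class = "icusurv_parameter_error")
  }
  if (any(diff(x) <= 0)) {
    rlang::abort("x must be strictly increasing", class = "icusurv_parameter_error")
  }
  q <- ceiling(span * n)
  if (n < degree + 1 || q < degree + 1) {
    rlang::abort(paste0(
      "Underdetermined local fit: neighbourhood of ", q,
      " point(s) cannot support a degree-", degree, " polynomial"),
      class = "icusurv_underdetermined_fit_error")
  }

  y_smooth <- vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    nb <- order(d, x)[seq_len(q)]
    d_max <- max(d[nb])
    w <- if (d_max > 0) (1 - pmin(d[nb] / d_max, 1)^3)^3 else rep(1, q)
    # centred design keeps the intercept equal to the fit at x[i]
    X <- outer(x[nb] - x[i], 0:degree, "^")
    fit <- stats::lm.wfit(X, y[nb], w)
    unname(fit$coefficients[1])
  }, double(1))

  if (any(!is.finite(y_smooth))) {
    rlang::abort("Local fit produced non-finite values",
                 class = "icusurv_underdetermined_fit_error")
  }
  out <- tibble::tibble(x = x, y_raw = y, y_smooth = y_smooth)
  attr(out, "span") <- span
  attr(out, "degree") <- degree
  attr(out, "family") <- "gaussian"
  attr(out, "iterations") <- 0L
  class(out) <- c("smooth_curve", class(out))
  out
}

#' Smooth a conditional survival curve for presentation
#'
#' Applies [loess_fit()] to the (day, conditional survival) points of a
#' curve, and with the same settings to the confidence bounds. Smoothing is
#' presentation-only: the exported statistics are always the unsmoothed
#' estimates, and the smoothed bounds exist solely to draw the dashed bands.
#'
#' Curves with fewer than 4 points are returned unsmoothed with a warning.
#'
#' @param curve A `cs_curve` from [estimate_conditional_survival()].
#' @param span LOESS span (default 0.5).
#' @param degree Local polynomial degree (default 2).
#' @return A `smooth_curve` tibble with columns `day`, `cs_raw`,
#'   `cs_smooth`, `ci_lower_smooth`, `ci_upper_smooth`.
#' @export
smooth_curve <- function(curve, span = 0.5, degree = 2) {
  smoothed <- nrow(curve) >= 4
  if (!smoothed) {
    rlang::warn(paste0("Curve '", attr(curve, "label") %||% "curve", "' has ",
                       nrow(curve), " point(s); returned unsmoothed"))
    out <- tibble::tibble(day = curve$day, cs_raw = curve$cs,
                          cs_smooth = curve$cs,
                          ci_lower_smooth = curve$ci_lower,
                          ci_upper_smooth = curve$ci_upper)
  } else {
    fit <- loess_fit(curve$day, curve$cs, span = span, degree = degree)
    lo <- loess_fit(curve$day, curve$ci_lower, span = span, degree = degree)
    hi <- loess_fit(curve$day, curve$ci_upper, span = span, degree = degree)
    out <- tibble::tibble(day = curve$day, cs_raw = curve$cs,
                          cs_smooth = fit$y_smooth,
                          ci_lower_smooth = lo$y_smooth,
                          ci_upper_smooth = hi$y_smooth)
  }
  attr(out, "span") <- span
  attr(out, "degree") <- degree
  attr(out, "family") <- "gaussian"
  attr(out, "iterations") <- 0L
  attr(out, "smoothed") <- smoothed
  attr(out, "label") <- attr(curve, "label")
  class(out) <- c("smooth_curve", class(out))
  out
}
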