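#' Agresti-Coull binomial confidence interval
#'
#' Approximate confidence interval for a binomial proportion. With
#' `z = qnorm((1 + conf) / 2)`, the adjusted sample size is
#' `n_tilde = n + z^2` and the adjusted proportion
#' `p_tilde = (x + z^2 / 2) / n_tilde`; the interval is
#' `p_tilde +/- z * sqrt(p_tilde * (1 - p_tilde) / n_tilde)`, clipped to
#' \[0, 1\]. The exact normal quantile is used throughout (for 95%,
#' z = 1.959964), not the z = 2 classroom shortcut.
#'
#' The interval is centred at `p_tilde`, so the raw proportion `x / n` may
#' sit off-centre; downstream code always reports `x / n` as the point
#' estimate and uses this interval only for its bounds.
#'
#' @param x Number of successes (vectorised).
#' @param n Number of trials (vectorised; must be >= 1).
#' @param conf Confidence level in (0, 1); default 0.95.
#' @return A tibble with columns `x`, `n`, `conf`, `p_tilde`, `lower`,
#'   `upper`, one row per input.
#' @export
#' @examples
#' agresti_coull(5, 10)
#' agresti_coull(34255, 38532)
agresti_coull <- function(x, n, conf = 0.95) {
  if (length(conf) != 1 || !is.finite(conf) || conf <= 0 || conf >= 1) {
    rlang::abort("conf must be a single value in (0, 1)",
                 class = "icusurv_parameter_error")
  }
  if (any(!is.finite(x)) || any(!is.finite(n))) {
    rlang::abort("x and n must be finite", class = "icusurv_parameter_error")
  }
  if (any(n < 1)) {
    rlang::abort("Agresti-Coull interval undefined for n = 0 trials",
                 class = "icusurv_undefined_interval_error")
  }
  if (any(x < 0) || any(x > n)) {
    rlang::abort("x must satisfy 0 <= x <= n", class = "icusurv_parameter_error")
  }
  z <- stats::qnorm((1 + conf) / 2)
  n_tilde <- n + z^2
  p_tilde <- (x + z^2 / 2) / n_tilde
  half <- z * sqrt(p_tilde * (1 - p_tilde) / n_tilde)
  tibble::tibble(
    x = x, n = n, conf = conf,
    p_tilde = p_tilde,
    lower = pmax(0, p_tilde - half),
    upper = pmin(1, p_tilde + half)
  )
}
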