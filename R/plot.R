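#' Plot a conditional survival curve
#'
#' Solid line for the per-day survival estimate, dashed lines for the
#' confidence bounds, day of ICU admission on the x axis and survival to
#' hospital discharge on the y axis.
#'
#' @param object A `cs_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cs_curve
#' @export
autoplot.cs_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (nrow(df) == 0) {
    rlang::abort("Cannot plot an empty curve", class = "icusurv_no_plot_error")
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$day))
  if (nrow(df) == 1) {
    rlang::warn("Curve has a single point; rendering points, no lines")
    p <- p +
      ggplot2::geom_point(ggplot2::aes(y = .data$cs)) +
      ggplot2::geom_point(ggplot2::aes(y = .data$ci_lower), shape = 1) +
      ggplot2::geom_point(ggplot2::aes(y = .data$ci_upper), shape = 1)
  } else {
    p <- p +
      ggplot2::geom_line(ggplot2::aes(y = .data$cs), linetype = "solid") +
      ggplot2::geom_line(ggplot2::aes(y = .data$ci_lower), linetype = "dashed") +
      ggplot2::geom_line(ggplot2::aes(y = .data$ci_upper), linetype = "dashed")
  }
  p +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Day of ICU admission",
                  y = "Survival to hospital discharge",
                  title = attr(object, "label")) +
    ggplot2::theme_classic()
}

#' Plot an analysis: overall or age-stratified panel
#'
#' The overall panel shows the (optionally LOESS-smoothed) survival curve as
#' a solid line with dashed confidence bands. The stratified panel overlays
#' the younger stratum (dot-dash line, dotted bands) on the older stratum
#' (solid line, dashed bands).
#'
#' @param object An `icusurv_analysis`.
#' @param which `"overall"` or `"stratified"`.
#' @param smoothed Draw the LOESS-smoothed lines (default `TRUE`); raw
#'   per-day estimates are drawn when `FALSE`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot icusurv_analysis
#' @export
autoplot.icusurv_analysis <- function(object, which = c("overall", "stratified"),
                                      smoothed = TRUE, ...) {
  which <- match.arg(which)
  get_df <- function(nm) {
    cv <- object$curves[[nm]]
    if (nrow(cv) == 0) return(NULL)
    sm <- object$smooths[[nm]]
    if (smoothed && !is.null(sm)) {
      tibble::tibble(day = sm$day, cs = sm$cs_smooth,
                     lower = sm$ci_lower_smooth, upper = sm$ci_upper_smooth)
    } else {
      tibble::tibble(day = cv$day, cs = cv$cs,
                     lower = cv$ci_lower, upper = cv$ci_upper)
    }
  }

  if (which == "overall") {
    df <- get_df("overall")
    if (is.null(df)) {
      rlang::abort("Overall curve is empty; nothing to plot",
                   class = "icusurv_no_plot_error")
    }
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$day)) +
      ggplot2::geom_line(ggplot2::aes(y = .data$cs), linetype = "solid") +
      ggplot2::geom_line(ggplot2::aes(y = .data$lower), linetype = "dashed") +
      ggplot2::geom_line(ggplot2::aes(y = .data$upper), linetype = "dashed")
  } else {
    young <- get_df("young")
    old <- get_df("old")
    if (is.null(young) && is.null(old)) {
      rlang::abort("Both stratum curves are empty; nothing to plot",
                   class = "icusurv_no_plot_error")
    }
    p <- ggplot2::ggplot(mapping = ggplot2::aes(x = .data$day))
    if (!is.null(young)) {
      p <- p +
        ggplot2::geom_line(data = young, ggplot2::aes(y = .data$cs),
                           linetype = "dotdash") +
        ggplot2::geom_line(data = young, ggplot2::aes(y = .data$lower),
                           linetype = "dotted") +
        ggplot2::geom_line(data = young, ggplot2::aes(y = .data$upper),
                           linetype = "dotted")
    }
    if (!is.null(old)) {
      p <- p +
        ggplot2::geom_line(data = old, ggplot2::aes(y = .data$cs),
                           linetype = "solid") +
        ggplot2::geom_line(data = old, ggplot2::aes(y = .data$lower),
                           linetype = "dashed") +
        ggplot2::geom_line(data = old, ggplot2::aes(y = .data$upper),
                           linetype = "dashed")
    }
  }
  p +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Day of ICU admission",
                  y = "Survival to hospital discharge",
                  title = object$config$label,
                  subtitle = if (which == "stratified") {
                    paste0("dot-dash: age < ", object$config$age_cutoff,
                           "; solid: age >= ", object$config$age_cutoff)
                  } else NULL) +
    ggplot2::theme_classic()
}

#' Write the figure files for an analysis
#'
#' Emits the overall panel and, when at least one stratum curve is
#' non-empty, the stratified panel, each in a vector format (SVG when the
#' build supports cairo, PDF otherwise) and as PNG.
#'
#' @param result An `icusurv_analysis`.
#' @param dir Output directory (created if needed).
#' @param dpi Raster resolution (default 300).
#' @param smoothed Plot smoothed lines (default `TRUE`).
#' @param width,height Figure size in inches.
#' @return Character vector of the files written, invisibly.
#' @export
plot_curves <- function(result, dir, dpi = 300, smoothed = TRUE,
                        width = 6, height = 4.5) {
  stopifnot(inherits(result, "icusurv_analysis"))
  if (all(vapply(result$curves, nrow, integer(1)) == 0)) {
    rlang::abort("All curves are empty; no figures to write",
                 class = "icusurv_no_plot_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vector_ext <- if (isTRUE(unname(capabilities("cairo")))) "svg" else "pdf"
  written <- character()
  panels <- list(overall = "overall")
  if (nrow(result$curves$young) > 0 || nrow(result$curves$old) > 0) {
    panels$stratified <- "stratified"
  }
  for (nm in names(panels)) {
    p <- autoplot(result, which = nm, smoothed = smoothed)
    for (ext in c(vector_ext, "png")) {
      path <- file.path(dir, paste0(nm, ".", ext))
      dev <- if (ext == "svg") grDevices::svg else ext
      suppressMessages(ggplot2::ggsave(path, p, device = dev, width = width,
                                       height = height, dpi = dpi))
      written <- c(written, path)
    }
  }
  invisible(written)
}
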