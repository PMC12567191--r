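# Coefficient report in the conventional three-section layout: first-order
# single-drug activity, drug-drug interactions, second-order single-drug
# activity.

#' Significance stars for p-values
#'
#' Conventional mapping: `*` for p < 0.05, `**` for p < 0.01, `***` for
#' p < 0.001, `****` for p < 0.0001, `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star codes.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Render the coefficient report of fitted endpoint models
#'
#' Produces the deterministic three-section term table: first-order
#' (linear) terms in drug order, interaction terms in lexicographic pair
#' order, then second-order (quadratic) terms in drug order, each with its
#' coefficient, standard error (the error bar of the bar chart) and
#' significance stars. Intercept-only models yield an intercept-only
#' report.
#'
#' @param models A `tgmo_model` or named list of them (one per endpoint).
#'
#' @return A `tgmo_report` tibble: `endpoint`, `section`, `term`, `beta`,
#'   `se`, `p_value`, `stars`.
#' @export
render_coefficient_report <- function(models) {
  if (inherits(models, "tgmo_model")) models <- list(models)
  out <- purrr::map_dfr(models, function(m) {
    tt <- m$terms
    section <- dplyr::case_when(
      tt$kind == "intercept" ~ "intercept",
      tt$kind == "linear" ~ "first_order",
      tt$kind == "interaction" ~ "interaction",
      tt$kind == "quadratic" ~ "second_order")
    rep_tbl <- tibble::tibble(endpoint = m$endpoint, section = section,
                              term = tt$label, i = tt$i, j = tt$j,
                              beta = tt$beta, se = tt$se,
                              p_value = tt$p_value,
                              stars = significance_stars(tt$p_value))
    sec_order <- c(intercept = 0, first_order = 1, interaction = 2,
                   second_order = 3)
    dplyr::arrange(rep_tbl, sec_order[.data$section], .data$i, .data$j)
  })
  class(out) <- c("tgmo_report", class(out))
  out
}

#' Write a coefficient report to CSV
#'
#' @param report A `tgmo_report` from [render_coefficient_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coefficient_report <- function(report, path) {
  readr::write_csv(as.data.frame(report), path)
  invisible(path)
}

#' Read back a coefficient report
#'
#' Round-trips the CSV written by [write_coefficient_report()].
#'
#' @param path CSV path.
#' @return A `tgmo_report` tibble.
#' @export
read_coefficient_report <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           endpoint = "c", section = "c", term = "c",
                           i = "i", j = "i", beta = "d", se = "d",
                           p_value = "d", stars = "c"))
  class(out) <- c("tgmo_report", class(out))
  out
}

#' Bar-chart of regression coefficients by section
#'
#' Coefficient bars with standard-error bars, faceted into the first-order,
#' interaction and second-order sections (left to right), one panel row per
#' endpoint.
#'
#' @param object A `tgmo_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tgmo_report
#' @export
autoplot.tgmo_report <- function(object, ...) {
  d <- dplyr::filter(object, .data$section != "intercept")
  d$section <- factor(d$section,
                      levels = c("first_order", "interaction",
                                 "second_order"))
  d$term <- factor(d$term, levels = unique(d$term))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$beta)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$beta < 0),
                      show.legend = FALSE) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$beta - .data$se,
                                        ymax = .data$beta + .data$se),
                           width = 0.3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), vjust = -0.6,
                       size = 3) +
    ggplot2::facet_grid(.data$endpoint ~ .data$section, scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = NULL, y = "regression coefficient") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' @method autoplot tgmo_model
#' @export
autoplot.tgmo_model <- function(object, ...) {
  autoplot(render_coefficient_report(object), ...)
}
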