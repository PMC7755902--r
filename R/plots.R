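#' Plot subtype prevalence per cohort
#'
#' @param prevalence Tibble from [subtype_prevalence()].
#' @return A ggplot object.
#' @export
plot_prevalence <- function(prevalence) {
  ggplot2::ggplot(prevalence,
                  ggplot2::aes(x = .data$subtype, y = .data$fraction,
                               fill = .data$cohort)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "Fraction of cohort", fill = "Cohort") +
    ggplot2::theme_minimal()
}

#' Plot Kaplan-Meier curves per group
#'
#' @param data Tibble with time, event and group columns.
#' @param time_col,event_col,group_col Column names.
#' @return A ggplot step-function plot.
#' @export
plot_km <- function(data, time_col = "survival_time", event_col = "event",
                    group_col = "group") {
  curves <- data |>
    dplyr::group_by(.data[[group_col]]) |>
    dplyr::group_modify(~ km_estimate(.x[[time_col]], .x[[event_col]])$curve) |>
    dplyr::ungroup()
  start <- curves |>
    dplyr::distinct(.data[[group_col]]) |>
    dplyr::mutate(time = 0, surv = 1)
  ggplot2::ggplot(dplyr::bind_rows(curves, start),
                  ggplot2::aes(x = .data$time, y = .data$surv,
                               colour = .data[[group_col]])) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Plot log2 odds ratios of gene-pair associations
#'
#' @param results Tibble from [pairwise_association()] or
#'   [bonferroni_filter()].
#' @return A ggplot tile plot.
#' @export
plot_comut <- function(results) {
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$gene_a, y = .data$gene_b,
                               fill = .data$log2_or)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 OR") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot per-sample signature exposures
#'
#' @param exposures Tibble from [refit_exposures()].
#' @return A stacked-bar ggplot of exposures for eligible samples.
#' @export
plot_exposures <- function(exposures) {
  carrier_calls(exposures, carrier_floor = -Inf) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$sample_id, y = .data$weight,
                                 fill = .data$signature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Exposure weight", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ER mixture fit
#'
#' Histogram of the fitted expression values with the two component
#' densities overlaid.
#'
#' @param object An `"er_mixfit"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.er_mixfit <- function(object, ...) {
  x <- object$data
  grid <- seq(min(x), max(x), length.out = 200)
  dens <- dplyr::bind_rows(
    tibble::tibble(x = grid, component = "neg",
                   d = object$lambda[which.min(object$means)] *
                     stats::dnorm(grid, min(object$means),
                                  object$sds[which.min(object$means)])),
    tibble::tibble(x = grid, component = "pos",
                   d = object$lambda[which.max(object$means)] *
                     stats::dnorm(grid, max(object$means),
                                  object$sds[which.max(object$means)])))
  ggplot2::ggplot() +
    ggplot2::geom_histogram(
      data = tibble::tibble(x = x),
      ggplot2::aes(x = .data$x, y = ggplot2::after_stat(density)),
      bins = 40, fill = "grey85", colour = "grey60") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(x = .data$x, y = .data$d,
                                    colour = .data$component)) +
    ggplot2::labs(x = "ESR1 expression", y = "Density",
                  colour = "Component") +
    ggplot2::theme_minimal()
}
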