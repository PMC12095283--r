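# ggplot2 displays: template topographies as sensor-space maps, and
# group comparisons of the temporal parameters.

#' Plot template topographies
#'
#' Sensor-space scalp maps (one facet per template), point color giving
#' the map value at each electrode over the schematic head layout.
#'
#' @param object An `ms_templates` with positions.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ms_templates
#' @export
autoplot.ms_templates <- function(object, ...) {
  d <- tidy(object)
  if (!"x2d" %in% names(d)) stop("templates carry no positions", call. = FALSE)
  ggplot2::ggplot(d, ggplot2::aes(.data$x2d, .data$y2d,
                                  color = .data$value)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_color_gradient2(low = "#2166AC", mid = "white",
                                   high = "#B2182B") +
    ggplot2::coord_fixed() +
    ggplot2::facet_wrap(~label) +
    ggplot2::theme_void() +
    ggplot2::labs(color = "a.u.")
}

#' Plot per-state parameters by group
#'
#' @param params Per-subject tidy parameter tibble (as produced by
#'   [run_group_analysis()]).
#' @param measure One of `"duration_ms"`, `"occurrence_hz"`,
#'   `"coverage_pct"`.
#' @return A ggplot (boxplots per state and group).
#' @export
plot_parameters <- function(params, measure = "duration_ms") {
  stopifnot(measure %in% names(params))
  ggplot2::ggplot(params, ggplot2::aes(.data$state, .data[[measure]],
                                       fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "microstate class", y = measure)
}

#' Plot a transition-probability matrix
#'
#' @param transitions Tidy transitions tibble with `from`, `to`,
#'   `probability` (averaged over subjects if repeated).
#' @return A ggplot tile map of the off-diagonal cells.
#' @export
plot_transitions <- function(transitions) {
  d <- dplyr::summarise(
    dplyr::group_by(transitions, .data$from, .data$to),
    probability = mean(.data$probability), .groups = "drop"
  )
  ggplot2::ggplot(d, ggplot2::aes(.data$to, .data$from,
                                  fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.3f", .data$probability)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#B2182B") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "to", y = "from", fill = "p")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
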