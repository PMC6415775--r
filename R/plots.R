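# ggplot2 displays for the main result types.

#' Plot an NMDS ordination
#'
#' @param ordination A `gd_ordination`.
#' @param labels Optional factor per sample for colouring.
#' @return A ggplot.
#' @export
plot_ordination <- function(ordination, labels = NULL) {
  dat <- ordination$coordinates
  if (!is.null(labels)) dat$group <- as.factor(labels)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2)) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      subtitle = sprintf("stress = %.3f", ordination$stress)) +
    ggplot2::theme_minimal()
  if (is.null(labels)) p + ggplot2::geom_point(alpha = 0.7)
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.7)
}

#' @export
autoplot.gd_ordination <- function(object, ...) plot_ordination(object, ...)

#' Plot the community-state transition graph
#'
#' Nodes at (month, cluster) sized by sample count; edges drawn for
#' transitions at or above the graph's display frequency.
#'
#' @param graph A `gd_transitions`.
#' @return A ggplot.
#' @export
plot_transitions <- function(graph) {
  shown <- graph$edges |> filter(!.data$hidden)
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = shown,
      ggplot2::aes(x = .data$from_month, y = .data$from_cluster,
                   xend = .data$to_month, yend = .data$to_cluster,
                   linewidth = .data$frequency),
      alpha = 0.4, colour = "steelblue") +
    ggplot2::geom_point(
      data = graph$nodes,
      ggplot2::aes(x = .data$month, y = .data$cluster, size = .data$n),
      colour = "grey25") +
    ggplot2::scale_linewidth(range = c(0.2, 1.6)) +
    ggplot2::scale_y_continuous(breaks = sort(unique(graph$nodes$cluster))) +
    ggplot2::labs(x = "age (months)", y = "community type",
                  size = "samples", linewidth = "frequency") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gd_transitions <- function(object, ...) plot_transitions(object)

#' Plot per-phase slopes
#'
#' Slope estimates with 95% intervals per response and phase; filled points
#' are significant at the report's level.
#'
#' @param report A `gd_phase_report`.
#' @return A ggplot.
#' @export
plot_phase_report <- function(report) {
  dat <- as_tibble(report)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$slope, y = .data$response)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$slope - 1.96 * .data$se,
                   xmax = .data$slope + 1.96 * .data$se), height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$significant),
                        shape = 21, size = 2.5) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black", `FALSE` = "white")) +
    ggplot2::facet_wrap(~phase) +
    ggplot2::labs(x = "slope per month", y = NULL, fill = "significant") +
    ggplot2::theme_minimal()
}

#' Plot a maturity model's predictions
#'
#' Microbiota age against chronological age with the identity line.
#'
#' @param predictions Tibble from [maz_score()] (needs `age_months` and
#'   `microbiota_age`).
#' @return A ggplot.
#' @export
plot_maturity <- function(predictions) {
  ggplot2::ggplot(predictions,
                  ggplot2::aes(x = .data$age_months, y = .data$microbiota_age)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(x = "chronological age (months)",
                  y = "microbiota age (months)") +
    ggplot2::theme_minimal()
}

#' Plot an envfit screening result
#'
#' Horizontal bars of variance explained (r2) per covariate and window;
#' asterisks mark FDR-significant fits.
#'
#' @param screen Tibble from [screen_covariates()].
#' @return A ggplot.
#' @export
plot_covariate_screen <- function(screen) {
  ggplot2::ggplot(screen,
                  ggplot2::aes(x = .data$r2, y = .data$covariate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(data = screen |> filter(.data$significant),
                       ggplot2::aes(label = "*"), nudge_x = 0.01, size = 5) +
    ggplot2::facet_wrap(~window, nrow = 1) +
    ggplot2::labs(x = expression(r^2), y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
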