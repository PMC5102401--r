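#' Boxplots of reserve extent and cost proportion by scenario
#'
#' @param experiment A [run_experiment()] result (or `per_solution_table()`
#'   output).
#' @return A ggplot: scenarios on the x axis in design order, one panel per
#'   metric.
#' @export
plot_extent_cost <- function(experiment) {
  tbl <- if (inherits(experiment, "reef_experiment"))
    per_solution_table(experiment) else experiment
  tbl <- tbl |>
    tidyr::pivot_longer(c("extent_km2", "cost_proportion"),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(code = factor(.data$code, levels = enumerate_scenarios()$code))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$code, y = .data$value,
                                    fill = .data$cost)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "scenario", y = NULL, fill = "cost layer") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @export
autoplot.reef_experiment <- function(object, ...) plot_extent_cost(object)

#' Ordination biplot of a constrained RDA
#'
#' Site scores on the first two constrained axes coloured by cost layer,
#' shaped by planning-unit size, with factor-level centroids overlaid.
#'
#' @param object A [rda_factors()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.reef_rda <- function(object, ...) {
  sc <- tibble::as_tibble(object$site_scores[, 1:2, drop = FALSE])
  names(sc) <- c("RDA1", "RDA2")
  sc <- dplyr::bind_cols(sc, object$labels)
  cen <- object$centroids
  ggplot2::ggplot(sc, ggplot2::aes(x = .data$RDA1, y = .data$RDA2)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$cost,
                                     shape = .data$pu_size), alpha = 0.6) +
    ggplot2::geom_point(data = cen, ggplot2::aes(x = .data$RDA1, y = .data$RDA2),
                        colour = "red", shape = 15, size = 2.5,
                        inherit.aes = FALSE) +
    ggplot2::labs(colour = "cost layer", shape = "PU size") +
    ggplot2::theme_minimal()
}

#' Incidental representation against reef-class rarity
#'
#' Scatter of expected representation (percent of each fine class's total
#' extent) against class rarity, with the representation objective as a
#' dashed line.
#'
#' @param records [expected_representation()] output, optionally with a
#'   `code` column to facet by coarse scenario.
#' @param objective_percent Objective line (default 30).
#' @return A ggplot.
#' @export
plot_representation <- function(records, objective_percent = 30) {
  p <- ggplot2::ggplot(records,
                       ggplot2::aes(x = .data$rarity_percent,
                                    y = .data$percent_of_class)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = objective_percent, linetype = "dashed") +
    ggplot2::labs(x = "reef-class rarity (%)",
                  y = "expected representation (% of class)") +
    ggplot2::theme_minimal()
  if ("code" %in% names(records)) p <- p + ggplot2::facet_wrap(~code)
  p
}

#' Heatmap of the nestedness grid
#'
#' @param grid [nestedness_grid()] output.
#' @return A ggplot tile map: coarse scenarios x test scenarios, faceted by
#'   threshold, filled by percent nested.
#' @export
plot_nestedness <- function(grid) {
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$coarse, y = .data$test,
                                     fill = .data$percent_nested)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.0f", .data$percent_nested)), size = 3) +
    ggplot2::facet_wrap(~threshold, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "coarse (large-PU) scenario", y = "test scenario",
                  fill = "% nested") +
    ggplot2::theme_minimal()
}
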