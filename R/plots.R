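# ggplot2 views of the main result objects.

#' Plot a bias-correction fit
#'
#' Scatter of observed versus modeled concentrations by region with each
#' region's composed adjustment line and the 1:1 line; the vertical gap to
#' the 1:1 line is the model's underprediction.
#'
#' @param object A `bias_fit` with training data.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bias_fit <- function(object, ...) {
  if (is.null(object$data)) {
    abort("This fit carries no training data (restored from disk?).")
  }
  eq <- suppressMessages(compose_adjustments(object))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$model_value,
                               y = .data$observed_value,
                               colour = .data$region)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey40") +
    ggplot2::geom_abline(
      data = eq,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$region)
    ) +
    ggplot2::labs(
      x = expression("Modeled aromatic SOA" ~ (mu * g / m^3)),
      y = expression("Observed aromatic SOA" ~ (mu * gC / m^3)),
      colour = "Region",
      title = "Regional bias of modeled aromatic SOA",
      subtitle = "Lines: composed adjustment equations; dotted: 1:1"
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of state-level attributable mortality
#'
#' @param report Output of [build_state_report()].
#' @param top_n Number of top-ranked states to display.
#' @return A ggplot object.
#' @export
plot_state_costs <- function(report, top_n = 15) {
  top <- report %>% filter(.data$rank <= top_n)
  ggplot2::ggplot(top,
                  ggplot2::aes(x = stats::reorder(.data$geography,
                                                  .data$cases_central),
                               y = .data$cases_central)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Attributable premature mortalities / yr",
                  title = "States ranked by attributable mortality") +
    ggplot2::theme_minimal()
}

#' Compare national estimates across concentration-response functions
#'
#' Point-range plot of central cases with 5th/95th percentile bars per CRF.
#'
#' @param national A tibble with `crf_label`, `cases_central`, `cases_p5`,
#'   `cases_p95` (e.g. `run_pipeline()$national`).
#' @return A ggplot object.
#' @export
plot_crf_comparison <- function(national) {
  ggplot2::ggplot(national,
                  ggplot2::aes(x = .data$crf_label,
                               y = .data$cases_central)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$cases_p5,
                                          ymax = .data$cases_p95)) +
    ggplot2::labs(x = "Concentration-response function",
                  y = "National premature mortalities / yr",
                  title = "CRF uncertainty in the national estimate") +
    ggplot2::theme_minimal()
}
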