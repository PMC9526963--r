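#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot power against the level-3 sample size
#'
#' Power curves over `n3`, one line per `(n2, n1)` combination, faceted by
#' the indirect-effect paths when the sweep covers several. A dashed line
#' marks the adequacy threshold.
#'
#' @param object A power result tibble from [estimate_power()] /
#'   [sweep_power()].
#' @param sided `"two"` (default) or `"one"`.
#' @param threshold Adequacy threshold drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot medpower_result
#' @export
autoplot.medpower_result <- function(object, sided = c("two", "one"),
                                     threshold = 0.8, ...) {
  sided <- match.arg(sided)
  df <- dplyr::mutate(
    tibble::as_tibble(object),
    power = .data[[paste0("power_", sided)]],
    series = paste0("n2=", .data$n2, ", n1=", .data$n1),
    effects = paste0("a3=", .data$a3, ", b3=", .data$b3)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$n3, y = .data$power,
                                        colour = .data$series,
                                        group = .data$series)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "level-3 clusters (n3)",
                  y = sprintf("power (%s-sided Sobel)", sided),
                  colour = "lower-level sizes") +
    ggplot2::theme_minimal()
  if (dplyr::n_distinct(df$effects) > 1) {
    p <- p + ggplot2::facet_wrap(~effects)
  }
  p
}

#' Plot the share of adequately powered designs by characteristic
#'
#' Bar chart of the proportion of designs reaching the adequacy threshold
#' for each value of each design characteristic, as produced by
#' [summarize_power_marginals()].
#'
#' @param marginals Output of [summarize_power_marginals()].
#' @return A ggplot object.
#' @export
plot_power_marginals <- function(marginals) {
  df <- dplyr::filter(marginals, .data$characteristic != "total")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$value),
                                   y = .data$prop_adequate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~characteristic, scales = "free_x") +
    ggplot2::labs(x = "parameter value", y = "proportion adequately powered") +
    ggplot2::theme_minimal()
}
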