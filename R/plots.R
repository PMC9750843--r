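#' Plot the relativized-F bias curve
#'
#' Mean relativized F against planting distance with 68% and 95% percentile
#' ribbons; the horizontal reference line at 1 marks spatial effects as large
#' as the intrinsic between-group differences.
#'
#' @param curve A [relative_f_curve()] result.
#' @return A ggplot object.
#' @export
plot_relative_f <- function(curve) {
  ribbons <- band_layers(curve, "rel_f")
  ggplot2::ggplot(tibble::as_tibble(curve), ggplot2::aes(x = .data$distance)) +
    ribbons +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", color = "grey55") +
    ggplot2::geom_line(ggplot2::aes(y = .data$rel_f_mean), linetype = "dashed") +
    ggplot2::labs(x = "Distance among plants (m)",
                  y = "Relativized F statistic",
                  title = "Group variation attributable to spatial interactions") +
    ggplot2::theme_minimal()
}

#' Plot the full/base correlation-convergence curve
#'
#' @param curve A [correlation_curve()] result.
#' @param r_threshold Threshold drawn as a horizontal reference (default 0.99).
#' @param recommendation Optional vertical line at the recommended distance.
#' @return A ggplot object.
#' @export
plot_correlation_curve <- function(curve, r_threshold = 0.99,
                                   recommendation = NULL) {
  p <- ggplot2::ggplot(tibble::as_tibble(curve),
                       ggplot2::aes(x = .data$distance)) +
    band_layers(curve, "r") +
    ggplot2::geom_hline(yintercept = r_threshold, linetype = "dotted") +
    ggplot2::geom_line(ggplot2::aes(y = .data$r_mean), linetype = "dashed") +
    ggplot2::labs(x = "Distance among plants (m)",
                  y = "Pearson correlation (full vs. base)",
                  title = "Agreement between spatial and non-spatial predictions") +
    ggplot2::theme_minimal()
  if (!is.null(recommendation) && !is.na(recommendation)) {
    p <- p + ggplot2::geom_vline(xintercept = recommendation,
                                 linetype = "dashed", color = "grey40")
  }
  p
}

band_layers <- function(curve, prefix) {
  levels <- sort(attr(curve, "band_levels") %||% c(0.68, 0.95),
                 decreasing = TRUE)
  lapply(seq_along(levels), function(i) {
    tag <- formatC(round(100 * levels[i]), width = 2, flag = "0")
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data[[paste0(prefix, "_lo_", tag)]],
                   ymax = .data[[paste0(prefix, "_hi_", tag)]]),
      fill = "steelblue", alpha = 0.25 + 0.2 * (i - 1)
    )
  })
}

#' Plot group mean growth under contrasting planting densities
#'
#' Dot-and-error-bar comparison of per-group predicted growth at two (or
#' more) distances, the display in which crowding-induced rank changes are
#' visible.
#'
#' @param group_means A tibble as produced by [bias_summary()]
#'   (`$group_means`) or by row-binding [group_summary()] results with a
#'   `distance` column.
#' @return A ggplot object.
#' @export
plot_group_means <- function(group_means) {
  df <- dplyr::mutate(tibble::as_tibble(group_means),
                      scenario = factor(paste0(.data$distance, " m")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean_growth,
                                   color = .data$scenario)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_growth - .data$sd_growth,
                   ymax = .data$mean_growth + .data$sd_growth),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::labs(x = NULL, y = expression(Predicted~growth~(m^3)),
                  color = "Spacing",
                  title = "Group performance under low vs. high planting density") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
autoplot.rel_f_curve <- function(object, ...) plot_relative_f(object)

#' @export
autoplot.cor_curve <- function(object, ...) plot_correlation_curve(object, ...)
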