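#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a trace
#'
#' @param object A [trace()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.noci_trace <- function(object, ...) {
  df <- as_trace_tibble(object)
  ylab <- sprintf("%s (%s)", object$kind, object$units)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = ylab) +
    ggplot2::theme_minimal()
}

#' Heatmap of a temperature-response matrix
#'
#' Rows are cells ordered by descending response to the hottest step;
#' color is dF/F0.
#'
#' @param object A [temperature_matrix()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.temperature_matrix <- function(object, ...) {
  m <- object$matrix
  df <- tidyr::expand_grid(row = seq_len(nrow(m)),
                           col = seq_len(ncol(m)))
  df$dff <- as.vector(t(m))[(df$row - 1) * ncol(m) + df$col]
  df$time <- object$time[df$col]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$row,
                                   fill = .data$dff)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "dF/F0") +
    ggplot2::labs(x = "time (s)", y = "cell (sorted)") +
    ggplot2::theme_minimal()
}

#' Stacked bar chart of mechanical-current classes
#'
#' @param summary Output of [mech_population_summary()], optionally with a
#'   `group` column when several populations are combined.
#' @return A ggplot.
#' @export
plot_mech_classes <- function(summary) {
  if (!"group" %in% names(summary)) summary$group <- "cells"
  summary$class_label <- factor(summary$class_label,
                                levels = c("RA", "IA", "SA", "NR"))
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$group, y = .data$fraction,
                               fill = .data$class_label)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_y_continuous(labels = function(x) 100 * x,
                                name = "% of neurons") +
    ggplot2::labs(x = NULL, fill = "class") +
    ggplot2::theme_minimal()
}

#' Sensitization-ratio summary plot
#'
#' @param ratios A tibble with `sens_ratio` and optionally a `condition`
#'   column (e.g. sensitizer identity).
#' @return A ggplot showing per-cell ratios with the sensitization
#'   threshold line.
#' @export
plot_sensitization <- function(ratios) {
  if (!"condition" %in% names(ratios)) ratios$condition <- "cells"
  ggplot2::ggplot(dplyr::filter(ratios, !is.na(.data$sens_ratio)),
                  ggplot2::aes(x = .data$condition, y = .data$sens_ratio)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, color = "red") +
    ggplot2::geom_hline(yintercept = 1.1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "peak 6 / peak 4") +
    ggplot2::theme_minimal()
}
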