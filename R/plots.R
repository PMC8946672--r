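#' Plot a fitted network
#'
#' Circle-layout network diagram: blue edges for positive regularized
#' partial correlations, red for negative, line width proportional to
#' |weight|. Layout is presentational only; the model is the weight
#' matrix.
#'
#' @param object An `rsi_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rsi_network <- function(object, ...) {
  p <- length(object$nodes)
  ang <- seq(0, 2 * pi, length.out = p + 1)[seq_len(p)]
  layout <- tibble::tibble(node = object$nodes,
                           x = cos(ang), y = sin(ang))
  edges <- tidy(object) |>
    dplyr::left_join(layout, by = c(from = "node")) |>
    dplyr::left_join(layout, by = c(to = "node"),
                     suffix = c("", "_to"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$x_to, yend = .data$y_to,
                   linewidth = abs(.data$weight),
                   colour = .data$weight > 0),
      alpha = 0.8
    ) +
    ggplot2::geom_point(data = layout,
                        ggplot2::aes(.data$x, .data$y), size = 10,
                        shape = 21, fill = "white") +
    ggplot2::geom_text(data = layout,
                       ggplot2::aes(.data$x, .data$y, label = .data$node),
                       size = 3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166AC",
                                            `FALSE` = "#B2182B"),
                                 guide = "none") +
    ggplot2::scale_linewidth(range = c(0.2, 2.5), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Plot bootstrapped edge-weight intervals
#'
#' Edges ordered by their full-sample weight, with the bootstrap mean
#' and the 95% percentile interval.
#'
#' @param object An `edge_bootstrap`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.edge_bootstrap <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::mutate(edge = paste0(.data$from, "-", .data$to)) |>
    dplyr::arrange(.data$estimate) |>
    dplyr::mutate(edge = factor(.data$edge, levels = .data$edge))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$edge)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0, colour = "grey50"
    ) +
    ggplot2::geom_point(ggplot2::aes(x = .data$estimate), colour = "#B2182B") +
    ggplot2::geom_point(ggplot2::aes(x = .data$boot_mean), colour = "black",
                        size = 0.8) +
    ggplot2::labs(x = "edge weight (partial correlation)", y = NULL)
}

#' Plot case-dropping stability curves
#'
#' Mean replicate-vs-original Strength correlation by drop proportion,
#' with the 5th-95th percentile band and the 0.7 qualification line.
#'
#' @param object A `case_drop`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.case_drop <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::group_by(.data$proportion) |>
    dplyr::summarise(
      mid = mean(.data$correlation, na.rm = TRUE),
      lo = quantile(.data$correlation, 0.05, na.rm = TRUE),
      hi = quantile(.data$correlation, 0.95, na.rm = TRUE),
      .groups = "drop"
    )
  ggplot2::ggplot(d, ggplot2::aes(.data$proportion, .data$mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$correlation_threshold,
                        linetype = 2) +
    ggplot2::labs(x = "proportion of cases dropped",
                  y = "correlation with full-sample Strength")
}

#' Plot centrality profiles
#'
#' Rescaled Strength / Closeness / Betweenness per node, one line per
#' network.
#'
#' @param centrality Tibble from [centrality_table()] (rows from
#'   several networks can be bound together).
#' @return A ggplot object.
#' @export
plot_centrality <- function(centrality) {
  d <- centrality |>
    dplyr::select("network_id", "node", dplyr::ends_with("_scaled")) |>
    tidyr::pivot_longer(dplyr::ends_with("_scaled"),
                        names_to = "index", values_to = "value") |>
    dplyr::mutate(index = sub("_scaled$", "", .data$index))
  ggplot2::ggplot(d, ggplot2::aes(.data$value, .data$node,
                                  colour = .data$network_id,
                                  group = .data$network_id)) +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~index) +
    ggplot2::labs(x = "rescaled centrality (1 = most important)",
                  y = NULL, colour = NULL)
}
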