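# ggplot2 displays for the main result types.

#' @describeIn spearman_matrix Heatmap of the signed correlation matrix with
#'   significance marks.
#' @param object A `coact_cormat`.
#' @param alpha Significance level marked on the heatmap.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.coact_cormat <- function(object, alpha = 0.05, ...) {
  long <- tidy.coact_cormat(object)
  long <- dplyr::bind_rows(
    long,
    dplyr::rename(long, region_i = "region_j", region_j = "region_i")
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$region_i, levels = object$regions),
    y = factor(.data$region_j, levels = rev(object$regions)),
    fill = .data$rho
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      ggplot2::aes(label = ifelse(!is.na(.data$p) & .data$p < alpha, "*", "")),
      size = 3
    ) +
    ggplot2::scale_fill_gradient2(
      low = "steelblue4", mid = "white", high = "firebrick3",
      limits = c(-1, 1), name = "rho"
    ) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @describeIn edge_composition Circular network diagram; edge width is
#'   `|rho|`, dashed edges are negative correlations, node size is degree.
#' @param object A `coact_network`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.coact_network <- function(object, ...) {
  g <- as_coact_igraph(object)
  lay <- igraph::layout_in_circle(g)
  nodes <- tibble::tibble(
    region = igraph::V(g)$name,
    x = lay[, 1], y = lay[, 2],
    degree = as.integer(igraph::degree(g))
  )
  p <- ggplot2::ggplot()
  if (nrow(object$edges) > 0) {
    edges <- object$edges |>
      dplyr::left_join(dplyr::select(nodes, "region", "x", "y"),
        by = c(from = "region")
      ) |>
      dplyr::left_join(dplyr::select(nodes, "region", xend = "x", yend = "y"),
        by = c(to = "region")
      ) |>
      dplyr::mutate(sign = ifelse(.data$rho > 0, "positive", "negative"))
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(
        x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
        linewidth = abs(.data$rho), linetype = .data$sign
      ),
      color = "grey40", alpha = 0.7
    )
  }
  p +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data$degree),
      color = "darkorange3"
    ) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x * 1.12, y = .data$y * 1.12, label = .data$region),
      size = 3
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5), guide = "none") +
    ggplot2::scale_linetype_manual(
      values = c(positive = "solid", negative = "dashed"), name = NULL
    ) +
    ggplot2::scale_size(range = c(1, 6), name = "degree") +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::theme_void()
}

#' @describeIn derived_effects Interval plot of the standardized effects.
#' @param object An `effect_summary`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.effect_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$estimate,
    y = factor(.data$effect, levels = rev(unique(.data$effect))),
    color = .data$type
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$conf.low, xmax = .data$conf.high
    )) +
    ggplot2::labs(
      x = "standardized effect (posterior mean, 95% CrI)", y = NULL,
      color = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot cumulative discrimination trajectories
#'
#' One line per animal of the cumulative D2 index over trials, with the
#' chance level 0 marked.
#'
#' @param trials Behavioral trial table (see [cumulative_d2()]).
#' @return A ggplot object.
#' @export
plot_d2_trajectories <- function(trials) {
  traj <- cumulative_d2(trials)
  ggplot2::ggplot(traj, ggplot2::aes(
    x = .data$trial, y = .data$d2, group = .data$animal_id
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "trial", y = "cumulative D2") +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_minimal()
}
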