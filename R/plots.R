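#' Plot serial killing curves
#'
#' Percent killing over time within each re-challenge round, one line per
#' product, faceted by round (the per-round re-anchoring makes rounds
#' directly comparable).
#'
#' @param pct A [percent_killing()] table.
#' @param et_ratio E:T ratio to display.
#' @return A ggplot object.
#' @export
plot_killing_curves <- function(pct, et_ratio = "2:1") {
  d <- pct[pct$et_ratio == et_ratio, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hours, y = .data$pct_killing,
                                  colour = .data$product)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~round, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Hours since re-challenge", y = "% killing",
                  title = paste("Serial killing at E:T", et_ratio)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a cluster profile
#'
#' Min-max-scaled marker intensity per cluster, rows and columns in the
#' average-linkage dendrogram order stored on the profile.
#'
#' @param object A [profile_clusters()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_profile <- function(object, ...) {
  d <- tidy(object)
  d$cluster <- factor(d$cluster,
                      levels = rownames(object$scaled)[object$row_order])
  d$marker <- factor(d$marker,
                     levels = colnames(object$scaled)[object$col_order])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$marker, y = .data$cluster,
                                  fill = .data$scaled)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Cluster", fill = "Scaled MFI") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Radar plot of product scorecards
#'
#' One polygon per product on the fixed axis order; the printed facet value
#' is the polygon area (arbitrary units, larger = better overall
#' performance).
#'
#' @param object A [build_scorecards()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scorecard_set <- function(object, ...) {
  radii <- attr(object, "radii")
  axes <- attr(object, "axes")
  m <- length(axes)
  theta <- 2 * pi * (seq_len(m) - 1) / m
  d <- as_tibble(radii, rownames = "product") |>
    tidyr::pivot_longer(-"product", names_to = "metric",
                        values_to = "radius") |>
    dplyr::mutate(
      angle = theta[match(.data$metric, axes)],
      x = .data$radius * cos(.data$angle),
      y = .data$radius * sin(.data$angle)
    ) |>
    dplyr::arrange(.data$product, .data$angle)
  lab <- tibble(product = object$product,
                label = sprintf("%s (area %.2f)", object$product,
                                object$area))
  d <- dplyr::left_join(d, lab, by = "product")
  spokes <- tibble(angle = theta, metric = axes,
                   x = cos(theta), y = sin(theta))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(data = spokes,
                          ggplot2::aes(x = 0, y = 0, xend = .data$x,
                                       yend = .data$y),
                          colour = "grey80") +
    ggplot2::geom_polygon(ggplot2::aes(group = .data$label),
                          fill = "steelblue", alpha = 0.4,
                          colour = "steelblue") +
    ggplot2::geom_text(data = spokes,
                       ggplot2::aes(x = 1.15 * .data$x, y = 1.15 * .data$y,
                                    label = .data$metric), size = 3) +
    ggplot2::facet_wrap(~label) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Delta mean abundance bar chart
#'
#' Per-cluster group difference in mean abundance; the subtraction
#' convention is read from the table's `convention` attribute and shown in
#' the subtitle.
#'
#' @param delta A [delta_mean_abundance()] table.
#' @return A ggplot object.
#' @export
plot_delta_abundance <- function(delta) {
  ggplot2::ggplot(delta, ggplot2::aes(x = .data$cluster, y = .data$delta,
                                      fill = .data$delta > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "Cluster", y = "Delta mean abundance (%)",
                  subtitle = attr(delta, "convention")) +
    ggplot2::theme_minimal()
}
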