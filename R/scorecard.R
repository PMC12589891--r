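#' Column-wise z-scaling of a product x metric matrix
#'
#' Standardises each metric across products to mean 0 and sample SD 1
#' (denominator n - 1), the scaling applied before radar-chart display so
#' axes with different units (frequencies in percent, integrated killing
#' values) become comparable.
#'
#' @param x Numeric matrix or data frame (products x metrics).
#' @return Matrix of z-scores with the input dimnames.
#' @export
#' @examples
#' zscale_metrics(cbind(freq = c(1, 3), iv = c(10, 30)))
zscale_metrics <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("At least two products are required for z-scaling.")
  s <- apply(x, 2, sd)
  zero <- which(s == 0 | !is.finite(s))
  if (length(zero)) {
    abort(paste0("Zero-variance metric(s): ",
                 paste(colnames(x)[zero] %||% zero, collapse = ", ")))
  }
  scale(x, center = TRUE, scale = TRUE)[, , drop = FALSE]
}

#' Radar polygon area
#'
#' Shoelace area of the polygon whose vertices lie at radius `r[i]` on `m`
#' equally spaced axes (angle `2 * pi / m` apart):
#' `0.5 * sin(2 * pi / m) * sum(r[i] * r[i + 1])` over the closed cycle.
#' Needs at least three axes and non-negative radii.
#'
#' @param radii Non-negative radius per axis, in axis order.
#' @return Polygon area (a.u.).
#' @export
#' @examples
#' polygon_area(rep(1, 4))  # unit square rotated 45 degrees: area 2
polygon_area <- function(radii) {
  m <- length(radii)
  if (m < 3) abort("At least 3 axes are required.")
  if (any(radii < 0) || any(!is.finite(radii))) {
    abort("All radii must be finite and non-negative.")
  }
  0.5 * sin(2 * pi / m) * sum(radii * radii[c(2:m, 1)])
}

#' Map z-scores to radar radii
#'
#' Per-axis min-max mapping of the cohort's z-scores onto
#' `[floor, 1]`: the cohort minimum maps to the floor, the maximum to 1.
#' The positive floor keeps every vertex off the origin so the polygon area
#' stays informative for the weakest product. This anchoring is a package
#' convention (reported areas are in arbitrary units and comparable only
#' within a cohort scored together).
#'
#' @param z Matrix of z-scores (products x axes).
#' @param floor Radius assigned to the per-axis minimum.
#' @return Matrix of radii in `[floor, 1]`.
#' @export
radial_map_minmax <- function(z, floor = 0.05) {
  z <- as.matrix(z)
  lo <- apply(z, 2, min)
  hi <- apply(z, 2, max)
  span <- hi - lo
  span[span == 0] <- 1
  u <- sweep(sweep(z, 2, lo), 2, span, "/")
  floor + (1 - floor) * u
}

#' Build product potency scorecards
#'
#' Combines the four boolean-signature frequencies with the 33-day IV at the
#' 2:1 E:T ratio into one five-axis scorecard per product: metrics are
#' z-scaled across the cohort, mapped to radii ([radial_map_minmax()]) in
#' the fixed axis order, and summarised as the radar polygon area — larger
#' area, greater overall performance. A product missing any metric is
#' excluded with a warning.
#'
#' @param metrics Tibble with one row per product: `product`, optional
#'   `product_group`, and one column per axis metric.
#' @param axes Axis metric columns in display order (cyclic rotations give
#'   identical areas; other permutations do not, so the order is fixed and
#'   recorded on the result).
#' @param floor Radial floor, see [radial_map_minmax()].
#' @return A `scorecard_set`: tibble `product`, `product_group`, `area`,
#'   with `z` and `radii` matrices, the axis order and floor as attributes.
#' @export
build_scorecards <- function(metrics,
                             axes = c("cytotoxicity", "activation",
                                      "infiltration", "resilience", "iv33"),
                             floor = 0.05) {
  missing_ax <- setdiff(axes, names(metrics))
  if (length(missing_ax)) {
    abort(paste0("Missing metric column(s): ",
                 paste(missing_ax, collapse = ", ")))
  }
  complete <- stats::complete.cases(metrics[, axes])
  if (any(!complete)) {
    warn(paste0("Excluding product(s) with missing metrics: ",
                paste(metrics$product[!complete], collapse = ", ")))
    metrics <- metrics[complete, , drop = FALSE]
  }
  x <- as.matrix(metrics[, axes])
  rownames(x) <- metrics$product
  z <- zscale_metrics(x)
  radii <- radial_map_minmax(z, floor = floor)
  area <- apply(radii, 1, polygon_area)
  out <- tibble(
    product = metrics$product,
    product_group = metrics$product_group %||% NA_character_,
    area = unname(area)
  )
  structure(out, class = c("scorecard_set", class(out)),
            z = z, radii = radii, metrics = x, axes = axes, floor = floor)
}

#' @rdname build_scorecards
#' @param x A `scorecard_set`.
#' @param ... Unused.
#' @export
tidy.scorecard_set <- function(x, ...) {
  z <- attr(x, "z"); radii <- attr(x, "radii"); raw <- attr(x, "metrics")
  long <- function(mat, name) {
    as_tibble(mat, rownames = "product") |>
      tidyr::pivot_longer(-"product", names_to = "metric", values_to = name)
  }
  long(raw, "value") |>
    dplyr::left_join(long(z, "z"), by = c("product", "metric")) |>
    dplyr::left_join(long(radii, "radius"), by = c("product", "metric")) |>
    dplyr::left_join(tibble(product = x$product, area = x$area,
                            product_group = x$product_group),
                     by = "product")
}

#' @rdname build_scorecards
#' @export
glance.scorecard_set <- function(x, ...) {
  tibble(
    n_products = nrow(x),
    n_axes = length(attr(x, "axes")),
    axes = paste(attr(x, "axes"), collapse = ","),
    floor = attr(x, "floor"),
    area_min = min(x$area), area_max = max(x$area)
  )
}

#' Group summary of scorecard metrics
#'
#' Per-metric mean by product group (e.g. CAR-only vs C7R co-expressing),
#' the summary radar comparing group-level functional performance.
#'
#' @param cards A `scorecard_set`.
#' @return Tibble `product_group`, `metric`, `mean_value`, `mean_z`,
#'   `mean_area`.
#' @export
scorecard_group_summary <- function(cards) {
  tidy(cards) |>
    dplyr::group_by(.data$product_group, .data$metric) |>
    dplyr::summarise(mean_value = mean(.data$value), mean_z = mean(.data$z),
                     mean_area = mean(.data$area), .groups = "drop")
}
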