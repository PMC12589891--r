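#' Quantify GFP-positive area in a fluorescence frame
#'
#' Thresholds a grayscale frame and counts above-threshold pixels, the
#' image-analysis step behind the serial killing readout. `method = "otsu"`
#' picks the threshold by Otsu's criterion (via EBImage); `method = "fixed"`
#' uses the supplied threshold. Area is in pixels squared, multiplied by
#' `pixel_size^2` when a calibration is given.
#'
#' @param frame Non-negative numeric matrix (2-D intensity image).
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold Fixed intensity threshold (required for
#'   `method = "fixed"`).
#' @param pixel_size Physical pixel edge length (default 1: area in px^2).
#' @return Scalar area.
#' @export
quantify_gfp_area <- function(frame, method = c("otsu", "fixed"),
                              threshold = NULL, pixel_size = 1) {
  method <- match.arg(method)
  frame <- as.matrix(frame)
  if (any(frame < 0)) abort("Intensity frame must be non-negative.")
  if (method == "fixed") {
    if (is.null(threshold)) abort("`threshold` is required for method = 'fixed'.")
    th <- threshold
  } else {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      abort("EBImage is required for Otsu thresholding.")
    }
    hi <- max(frame)
    if (hi == 0) return(0)
    th <- EBImage::otsu(EBImage::Image(frame / hi), range = c(0, 1)) * hi
  }
  sum(frame >= th & frame > 0) * pixel_size^2
}

#' Per-frame percent killing from GFP areas
#'
#' Normalises each round's areas to its anchor frame (the first frame after
#' re-challenge, `t1`) and reports killing as
#' `100 - (area / area_t1) * 100`: 0 at the anchor, 100 at full clearance,
#' and negative under net tumor growth (values are not clamped, so growth
#' penalises downstream scores). Rounds whose anchor area is 0 are undefined
#' and flagged `NA` with a warning.
#'
#' @param series Long tibble with columns `product`, `et_ratio`, `round`,
#'   `hours`, `area` (e.g. from [simulate_killing_series()] or a plate
#'   export).
#' @return The input plus `area_t1` and `pct_killing` columns.
#' @export
#' @examples
#' ks <- simulate_killing_series(killing_params())
#' head(percent_killing(ks))
percent_killing <- function(series) {
  req <- c("product", "et_ratio", "round", "hours", "area")
  missing_cols <- setdiff(req, names(series))
  if (length(missing_cols)) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  out <- series |>
    dplyr::group_by(.data$product, .data$et_ratio, .data$round) |>
    dplyr::mutate(area_t1 = .data$area[which.min(.data$hours)]) |>
    dplyr::ungroup() |>
    dplyr::mutate(pct_killing = ifelse(.data$area_t1 > 0,
                                       100 - (.data$area / .data$area_t1) * 100,
                                       NA_real_))
  if (anyNA(out$pct_killing)) {
    warn("Rounds with zero anchor area give undefined percent killing (NA).")
  }
  out
}

#' Per-round 3-day integrated killing values
#'
#' The 3-day integrated value (IV) sums a round's per-frame percent-killing
#' values (the anchor frame contributes 0), in units of percent x frames.
#' Missing frames are summed over what is available, with a warning when
#' rounds have unequal frame counts.
#'
#' @param pct A [percent_killing()] table.
#' @return Tibble `product`, `et_ratio`, `round`, `n_frames`, `iv3`.
#' @export
killing_iv3 <- function(pct) {
  if (!"pct_killing" %in% names(pct)) pct <- percent_killing(pct)
  out <- pct |>
    dplyr::group_by(.data$product, .data$et_ratio, .data$round) |>
    dplyr::summarise(n_frames = dplyr::n(),
                     iv3 = sum(.data$pct_killing), .groups = "drop")
  if (length(unique(out$n_frames)) > 1) {
    warn("Unequal frame counts across rounds; IVs summed over available frames.")
  }
  out
}

#' 33-day integrated killing value
#'
#' The serial-killing score per product and E:T ratio: the sum of the eleven
#' 3-day IVs (fewer rounds are summed with a warning). Products are rankable
#' by this score; it is linear in the per-frame percentages and strictly
#' increasing in kill rate at fixed growth.
#'
#' @param pct A [percent_killing()] (or raw area) table.
#' @param expected_rounds Warn when fewer rounds are present.
#' @return Tibble `product`, `et_ratio`, `n_rounds`, `iv33`.
#' @export
#' @examples
#' ks <- simulate_killing_series(killing_params(kill_rate = 0.08))
#' killing_iv33(percent_killing(ks))
killing_iv33 <- function(pct, expected_rounds = 11) {
  iv3 <- if (all(c("iv3", "round") %in% names(pct))) pct else killing_iv3(pct)
  out <- iv3 |>
    dplyr::group_by(.data$product, .data$et_ratio) |>
    dplyr::summarise(n_rounds = dplyr::n(),
                     iv33 = sum(.data$iv3), .groups = "drop")
  if (any(out$n_rounds < expected_rounds)) {
    warn(paste0("Fewer than ", expected_rounds,
                " rounds present; 33-day IV summed over available rounds."))
  }
  out
}
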