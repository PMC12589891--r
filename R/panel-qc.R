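#' Stain index
#'
#' Resolution metric for an antibody/dilution:
#' `SI = (MFI_positive - MFI_negative) / (2 * SD_negative)`, where MFI is
#' the mean fluorescence intensity of the stained-positive and negative
#' populations and SD the negative population's standard deviation. MFI is
#' the arithmetic mean by default (`center = "median"` offered as a robust
#' option). Scale-invariant under a common multiplicative rescaling of the
#' intensities.
#'
#' @param mfi_positive,mfi_negative Population MFIs (or raw intensity
#'   vectors, from which mean/SD are computed).
#' @param sd_negative Negative-population SD (> 0); ignored when raw
#'   vectors are given.
#' @param center `"mean"` or `"median"` (for raw-vector input).
#' @return Scalar stain index.
#' @export
#' @examples
#' stain_index(1000, 100, 45)  # 10
stain_index <- function(mfi_positive, mfi_negative, sd_negative = NULL,
                        center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(mfi_positive) > 1 || length(mfi_negative) > 1) {
    loc <- if (center == "mean") mean else median
    sd_negative <- sd(mfi_negative)
    mfi_positive <- loc(mfi_positive)
    mfi_negative <- loc(mfi_negative)
  }
  if (is.null(sd_negative) || !is.finite(sd_negative) || sd_negative <= 0) {
    abort("`sd_negative` must be a positive number.")
  }
  (mfi_positive - mfi_negative) / (2 * sd_negative)
}

#' Select the optimal antibody dilution
#'
#' Titration rule: compute the stain index for each dilution and pick the
#' argmax; ties go to the most dilute candidate (equal resolution at lower
#' antibody cost). Order of the input series does not change the choice
#' beyond that tie rule.
#'
#' @param titration Tibble with columns `dilution` (character labels, most
#'   concentrated first unless `dilution_rank` given), `mfi_positive`,
#'   `mfi_negative`, `sd_negative`.
#' @param dilution_rank Optional numeric rank, higher = more dilute;
#'   defaults to the row order.
#' @return One-row tibble: the winning dilution with its stain index.
#' @export
select_titration <- function(titration, dilution_rank = NULL) {
  if (nrow(titration) == 0) abort("At least one dilution is required.")
  si <- mapply(stain_index, titration$mfi_positive, titration$mfi_negative,
               titration$sd_negative)
  rank <- dilution_rank %||% seq_len(nrow(titration))
  best <- which(si == max(si))
  pick <- best[which.max(rank[best])]
  tibble(dilution = titration$dilution[pick], stain_index = si[pick])
}

#' FMO variability across donors
#'
#' Panel-consistency check on fluorescence-minus-one controls: the sample
#' SD of each marker's positive-cell frequency across donors, passing when
#' below 8 percentage points (frequencies and the threshold are both in
#' percentage points).
#'
#' @param freqs Tibble `marker`, `donor`, `frequency` (percent), or a
#'   markers x donors matrix.
#' @param threshold Pass threshold in percentage points.
#' @return Tibble `marker`, `n_donors`, `sd`, `pass`; SD undefined (`NA`)
#'   with a single donor.
#' @export
#' @examples
#' fmo_variability(tibble::tibble(
#'   marker = rep("GrzB", 3), donor = c("d1", "d2", "d3"),
#'   frequency = c(12, 14, 13)
#' ))
fmo_variability <- function(freqs, threshold = 8) {
  if (is.matrix(freqs)) {
    freqs <- as_tibble(freqs, rownames = "marker") |>
      tidyr::pivot_longer(-"marker", names_to = "donor",
                          values_to = "frequency")
  }
  out <- freqs |>
    dplyr::group_by(.data$marker) |>
    dplyr::summarise(n_donors = dplyr::n(),
                     sd = if (dplyr::n() >= 2) sd(.data$frequency) else NA_real_,
                     .groups = "drop") |>
    dplyr::mutate(pass = .data$sd < threshold)
  if (any(out$n_donors < 2)) {
    warn("Markers with a single donor have undefined SD.")
  }
  out
}
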