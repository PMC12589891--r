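#' Functional cytokine group scores
#'
#' Collapses member cytokines into one score per (patient, group,
#' timepoint): the mean concentration, or the mean of log concentrations
#' (`log_scale = TRUE`) when fold-type behaviour is preferred. Scores are
#' permutation-invariant within a group; an empty group is a configuration
#' error.
#'
#' @param correlates A `correlate_set` (see [simulate_correlates()]) or a
#'   cytokine tibble with columns `patient`, `group`, `cytokine`,
#'   `timepoint`, `days`, `concentration`.
#' @param log_scale Average log-concentrations instead of concentrations.
#' @return Tibble `patient`, `group`, `timepoint`, `days`, `score`.
#' @export
cytokine_group_scores <- function(correlates, log_scale = FALSE) {
  cyt <- if (inherits(correlates, "correlate_set")) correlates$cytokines else correlates
  if (nrow(cyt) == 0 || anyNA(cyt$group)) {
    abort("Every scored cytokine must belong to a non-empty group.")
  }
  cyt |>
    dplyr::group_by(.data$patient, .data$group, .data$timepoint, .data$days) |>
    dplyr::summarise(
      score = if (log_scale) mean(log(.data$concentration)) else mean(.data$concentration),
      .groups = "drop"
    )
}

#' Timepoint deltas of group scores
#'
#' Later-minus-earlier changes for the standard contrasts pre-treatment to
#' week 1, pre-treatment to week 4, and week 1 to week 4 (configurable).
#' A missing timepoint gives a flagged `NA` delta.
#'
#' @param scores A [cytokine_group_scores()] table.
#' @param pairs List of `c(earlier, later)` timepoint pairs.
#' @return Tibble `patient`, `group`, `contrast`, `delta`.
#' @export
timepoint_deltas <- function(scores,
                             pairs = list(c("pre", "wk1"), c("pre", "wk4"),
                                          c("wk1", "wk4"))) {
  wide <- scores |>
    dplyr::select("patient", "group", "timepoint", "score") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "score")
  out <- purrr::map_dfr(pairs, function(p) {
    earlier <- if (p[1] %in% names(wide)) wide[[p[1]]] else NA_real_
    later <- if (p[2] %in% names(wide)) wide[[p[2]]] else NA_real_
    tibble(patient = wide$patient, group = wide$group,
           contrast = paste0(p[1], "_to_", p[2]),
           delta = later - earlier)
  })
  if (anyNA(out$delta)) warn("Missing timepoints give NA deltas.")
  out
}

#' Spearman association of cluster metrics with cytokine deltas
#'
#' Rank correlation (midranks for ties) between a per-patient cluster
#' metric and each (cytokine group, contrast) delta. Constant vectors give
#' an undefined correlation, returned `NA` and flagged. Reported without
#' multiplicity correction and labelled exploratory; `adjust = "BH"` adds
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param metrics Tibble `patient`, `cluster_metric` (or name via
#'   `metric_col`).
#' @param deltas A [timepoint_deltas()] table.
#' @param metric_col Metric column name.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble `group`, `contrast`, `n`, `rho`, `p_value`, `defined`,
#'   `analysis` (always `"exploratory"`), plus `p_adjusted` when requested.
#' @export
spearman_assoc <- function(metrics, deltas, metric_col = "cluster_metric",
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  joined <- dplyr::inner_join(deltas, metrics[, c("patient", metric_col)],
                              by = "patient")
  out <- joined |>
    dplyr::group_by(.data$group, .data$contrast) |>
    dplyr::summarise(
      n = sum(!is.na(.data$delta)),
      rho = {
        x <- .data[[metric_col]][!is.na(.data$delta)]
        y <- .data$delta[!is.na(.data$delta)]
        if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) NA_real_
        else suppressWarnings(cor(x, y, method = "spearman"))
      },
      p_value = {
        x <- .data[[metric_col]][!is.na(.data$delta)]
        y <- .data$delta[!is.na(.data$delta)]
        if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) NA_real_
        else suppressWarnings(cor.test(x, y, method = "spearman")$p.value)
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(defined = !is.na(.data$rho), analysis = "exploratory")
  if (any(!out$defined)) warn("Constant vectors give undefined correlations (NA).")
  if (adjust == "BH") out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out
}

#' Trapezoidal persistence AUC
#'
#' Area under a longitudinal transgene-level curve by the trapezoid rule on
#' the measurement grid in days (3 h sits at 0.125 days). Additive over
#' adjacent intervals; timepoints must be strictly increasing.
#'
#' @param days Measurement times (days).
#' @param level Transgene levels at `days`.
#' @return Scalar AUC (level-units x days).
#' @export
#' @examples
#' persistence_auc(c(0, 28), c(2, 2))  # 56
persistence_auc <- function(days, level) {
  if (length(days) < 2) abort("At least two timepoints are required.")
  if (is.unsorted(days, strictly = TRUE)) {
    abort("Timepoints must be strictly increasing.")
  }
  pracma::trapz(days, level)
}

#' Per-patient persistence AUCs
#'
#' @param correlates A `correlate_set` or a persistence tibble with
#'   `patient`, `days`, `level`.
#' @return Tibble `patient`, `auc`.
#' @export
persistence_auc_by_patient <- function(correlates) {
  pers <- if (inherits(correlates, "correlate_set")) correlates$persistence else correlates
  pers |>
    dplyr::group_by(.data$patient) |>
    dplyr::arrange(.data$days, .by_group = TRUE) |>
    dplyr::summarise(auc = persistence_auc(.data$days, .data$level),
                     .groups = "drop")
}

#' Pearson correlation with linear regression
#'
#' Pearson r with its t-based p-value and 95% confidence interval, plus the
#' ordinary-least-squares slope/intercept with a 95% CI on the slope — the
#' analysis relating composite scorecard areas to in vivo persistence AUCs.
#' Zero variance in either variable is undefined and flagged.
#'
#' @param x,y Paired numeric vectors (at least 3 pairs).
#' @param conf_level Confidence level.
#' @return One-row tibble: `n`, `r`, `r_conf_low`, `r_conf_high`, `p_value`,
#'   `slope`, `intercept`, `slope_conf_low`, `slope_conf_high`,
#'   `significant` (at p < 0.05), `defined`.
#' @export
pearson_regression <- function(x, y, conf_level = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) abort("At least 3 paired observations are required.")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Zero variance; correlation undefined.")
    return(tibble(n = length(x), r = NA_real_, r_conf_low = NA_real_,
                  r_conf_high = NA_real_, p_value = NA_real_,
                  slope = NA_real_, intercept = NA_real_,
                  slope_conf_low = NA_real_, slope_conf_high = NA_real_,
                  significant = NA, defined = FALSE))
  }
  ct <- cor.test(x, y, method = "pearson", conf.level = conf_level)
  fit <- lm(y ~ x)
  ci <- confint(fit, "x", level = conf_level)
  tibble(
    n = length(x),
    r = unname(ct$estimate),
    r_conf_low = if (!is.null(ct$conf.int)) ct$conf.int[1] else NA_real_,
    r_conf_high = if (!is.null(ct$conf.int)) ct$conf.int[2] else NA_real_,
    p_value = ct$p.value,
    slope = unname(stats::coef(fit)["x"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    slope_conf_low = ci[1], slope_conf_high = ci[2],
    significant = ct$p.value < 0.05,
    defined = TRUE
  )
}
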