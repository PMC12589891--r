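#' Simulate cytometry event tables for a cohort
#'
#' Draws one sample per (donor, condition) from a log-normal mixture of
#' [population_spec()] components. Each event gets raw marker intensities
#' from its population's log-normal model (activation shifts applied in the
#' stimulated condition), an acquisition-time value, and independent CAR/C7R
#' transduction calls at the configured fractions; the transgene-detection
#' channels are bright for transduced events and dim otherwise. Product-group
#' structure is induced by reweighting: C7R-group products are enriched for
#' the CD8 effector populations, CAR-only products for exhausted/
#' unconventional subsets, so downstream group comparisons have a known
#' direction.
#'
#' The ground-truth population label is stored in the `.population` column,
#' which is metadata: clustering and profiling operations only ever see the
#' marker channels selected by [clustering_markers()].
#'
#' @param cohort A [cohort_config()].
#' @param populations List of [population_spec()]; weights are renormalised
#'   per sample.
#' @param group_enrichment Multiplier applied to CD8 effector population
#'   weights in C7R-group products (and its inverse to exhausted/
#'   unconventional weights); 1 disables group structure.
#' @return One tibble with all samples: metadata columns (`sample_id`,
#'   `donor`, `condition`, `product_group`, `outcome`, `car_pos`, `c7r_pos`,
#'   `.population`, `time`) plus one column per panel marker (raw a.u.;
#'   `scale_state` attribute `"raw"`). Zero donors give an empty tibble.
#' @export
#' @examples
#' ev <- simulate_event_tables(cohort_config(n_donors = 2, events_per_sample = 500))
#' dplyr::count(ev, sample_id)
simulate_event_tables <- function(cohort,
                                  populations = default_populations(),
                                  group_enrichment = 1.6) {
  if (length(populations) == 0) {
    abort("`populations` must contain at least one population_spec.")
  }
  panel <- default_panel()
  if (length(cohort$donors) == 0) {
    out <- tibble()
    return(set_event_attrs(out, markers = panel, state = "raw"))
  }
  effector <- c("cd8_cytotoxic", "cd8_activated", "cd8_infiltrating",
                "cd8_resilient")
  dysfunction <- c("cd4_exhausted", "dn_unconventional")

  samples <- tidyr::expand_grid(
    donor_i = seq_along(cohort$donors),
    condition = cohort$conditions
  )

  withr::with_seed(cohort$seed, {
    parts <- purrr::pmap(samples, function(donor_i, condition) {
      donor <- cohort$donors[donor_i]
      group <- cohort$groups[donor_i]
      n <- cohort$events_per_sample

      w <- vapply(populations, `[[`, numeric(1), "weight")
      names(w) <- vapply(populations, `[[`, character(1), "name")
      if (group == "C7R") {
        w[names(w) %in% effector] <- w[names(w) %in% effector] * group_enrichment
        w[names(w) %in% dysfunction] <- w[names(w) %in% dysfunction] / group_enrichment
      } else {
        w[names(w) %in% effector] <- w[names(w) %in% effector] / group_enrichment
        w[names(w) %in% dysfunction] <- w[names(w) %in% dysfunction] * group_enrichment
      }
      w <- w / sum(w)

      pop_idx <- sample.int(length(populations), n, replace = TRUE, prob = w)
      values <- matrix(0, nrow = n, ncol = length(panel),
                       dimnames = list(NULL, panel))
      for (p in seq_along(populations)) {
        rows <- which(pop_idx == p)
        if (length(rows) == 0) next
        spec <- populations[[p]]
        mu <- setNames(rep(spec$log_mean_low, length(panel)), panel)
        mu[intersect(spec$high, panel)] <- spec$log_mean_high
        if (condition == "stim" && length(spec$activation_shift)) {
          sh <- spec$activation_shift
          mu[names(sh)] <- mu[names(sh)] + sh
        }
        for (ch in setdiff(panel, c("CAR-14g2a", "C7R-CD34"))) {
          values[rows, ch] <- rlnorm(length(rows), mu[ch], spec$log_sd)
        }
      }

      car_pos <- rbinom(n, 1L, cohort$car_positive_fraction)
      c7r_frac <- if (group == "C7R") cohort$c7r_positive_fraction else 0
      c7r_pos <- rbinom(n, 1L, c7r_frac)
      values[, "CAR-14g2a"] <- rlnorm(n, ifelse(car_pos == 1, log(4000), log(40)), 0.35)
      values[, "C7R-CD34"] <- rlnorm(n, ifelse(c7r_pos == 1, log(4000), log(40)), 0.35)
      # Viability dye: dim = viable; all simulated events are viable T cells.
      values[, "Viability"] <- rlnorm(n, log(30), 0.3)

      dplyr::bind_cols(
        tibble(
          sample_id = paste(donor, condition, sep = "_"),
          donor = donor, condition = condition, product_group = group,
          outcome = cohort$outcomes[donor_i],
          car_pos = car_pos, c7r_pos = c7r_pos,
          .population = names(w)[pop_idx],
          time = seq_len(n)
        ),
        as_tibble(values)
      )
    })
    out <- dplyr::bind_rows(parts)
  })
  set_event_attrs(out, markers = panel, state = "raw")
}
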