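#' Post-treatment measurement grid
#'
#' The five longitudinal timepoints used for cytokine and transgene
#' persistence measurements: pre-treatment, 3 hours, and weeks 1, 2 and 4
#' post-infusion, with their positions in days (3 h = 0.125 days).
#'
#' @return Tibble with columns `timepoint`, `days`.
#' @export
correlate_timepoints <- function() {
  tibble(
    timepoint = factor(c("pre", "3h", "wk1", "wk2", "wk4"),
                       levels = c("pre", "3h", "wk1", "wk2", "wk4")),
    days = c(0, 0.125, 7, 14, 28)
  )
}

#' Default functional cytokine grouping
#'
#' Cytokines grouped into biologically motivated categories; membership is
#' configuration, not a measurement.
#'
#' @return Tibble with columns `cytokine`, `group`.
#' @export
default_cytokine_grouping <- function() {
  tibble(
    cytokine = c("IFN-g", "TNF-a", "IL-6", "IL-10", "TGF-b", "IL-7", "IL-15"),
    group = c("inflammatory", "inflammatory", "inflammatory",
              "regulatory", "regulatory", "homeostatic", "homeostatic")
  )
}

#' Simulate post-treatment correlates with known ground truth
#'
#' Generates the three linked tables the association stage consumes. Each
#' patient carries a latent responsiveness factor; a per-product cluster
#' metric equals that factor (plus optional noise), and each cytokine group's
#' concentrations follow `baseline * exp(effect * latent * course(t))` with
#' optional log-normal noise, where `course(t)` rises from 0 pre-treatment to
#' a week-1 peak and wanes. Positive `group_effects` therefore plant a
#' positive cluster-to-cytokine-delta association of known direction.
#' Transgene persistence follows a linear rise to a week-1 peak then
#' exponential decay, with the peak scaled by the latent factor.
#'
#' @param cohort A [cohort_config()]; one patient per donor.
#' @param group_effects Named effect sizes per cytokine group (log scale per
#'   unit latent factor).
#' @param grouping Cytokine-to-group map, default
#'   [default_cytokine_grouping()].
#' @param baseline Baseline concentration (pg/mL a.u.).
#' @param noise_sd Log-normal measurement noise SD (0 = noise-free).
#' @param persistence_peak Transgene level at the week-1 peak for latent
#'   factor 0 (copies/ug a.u.).
#' @param persistence_decay Exponential decay rate per day after the peak.
#' @param seed Integer seed.
#' @return A list of class `correlate_set`: `$cytokines` (patient x cytokine
#'   x timepoint concentrations), `$grouping`, `$persistence` (patient x
#'   timepoint transgene levels), `$metrics` (per-patient cluster metric with
#'   product group/outcome; `.latent` holds the hidden factor).
#' @export
simulate_correlates <- function(cohort,
                                group_effects = c(inflammatory = 0.8,
                                                  regulatory = -0.4,
                                                  homeostatic = 0),
                                grouping = default_cytokine_grouping(),
                                baseline = 100, noise_sd = 0.1,
                                persistence_peak = 1000,
                                persistence_decay = 0.12,
                                seed = cohort$seed) {
  tp <- correlate_timepoints()
  patients <- cohort$donors
  course <- c(pre = 0, `3h` = 0.3, wk1 = 1, wk2 = 0.7, wk4 = 0.4)

  withr::with_seed(seed, {
    latent <- rnorm(length(patients), 0, 1)
    metrics <- tibble(
      patient = patients,
      product_group = cohort$groups,
      outcome = cohort$outcomes,
      cluster_metric = latent + rnorm(length(patients), 0, noise_sd),
      .latent = latent
    )

    cyt <- tidyr::expand_grid(patient = patients, cytokine = grouping$cytokine) |>
      dplyr::left_join(grouping, by = "cytokine") |>
      tidyr::expand_grid(tp)
    eff <- group_effects[cyt$group]
    eff[is.na(eff)] <- 0
    lat <- latent[match(cyt$patient, patients)]
    mu <- baseline * exp(eff * lat * course[as.character(cyt$timepoint)])
    noise <- if (noise_sd > 0) rlnorm(nrow(cyt), 0, noise_sd) else 1
    cyt$concentration <- unname(mu * noise)

    pers <- tidyr::expand_grid(patient = patients, tp)
    peak <- persistence_peak * exp(0.5 * latent[match(pers$patient, patients)])
    t_peak <- 7
    level <- ifelse(pers$days <= t_peak,
                    peak * pers$days / t_peak,
                    peak * exp(-persistence_decay * (pers$days - t_peak)))
    pnoise <- if (noise_sd > 0) rlnorm(nrow(pers), 0, noise_sd) else 1
    pers$level <- unname(level * pnoise)
  })

  structure(
    list(cytokines = dplyr::select(cyt, "patient", "group", "cytokine",
                                   "timepoint", "days", "concentration"),
         grouping = grouping,
         persistence = pers,
         metrics = metrics),
    class = "correlate_set"
  )
}
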