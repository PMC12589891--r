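#' Specify a synthetic T cell population
#'
#' A population is a log-normal mixture component on the raw intensity scale:
#' each marker has a location (`log_mean`, natural-log of the typical raw
#' intensity) and spread (`log_sd`). Markers not named default to a dim
#' baseline. `activation_shift` is an additive shift on the log-location,
#' applied only to events simulated in the stimulated condition (models
#' antigen-driven upregulation of activation markers).
#'
#' @param name Population label.
#' @param weight Mixture weight per sample before per-group modifiers;
#'   weights are renormalised to sum to 1 within each sample.
#' @param high Character vector of markers expressed highly by this
#'   population.
#' @param log_mean_low,log_mean_high Log-locations for baseline and high
#'   markers (raw intensity a.u.).
#' @param log_sd Per-marker log-scale spread (> 0).
#' @param activation_shift Named numeric vector of additive log-location
#'   shifts applied in the stimulated condition only.
#' @return A `population_spec` list.
#' @export
population_spec <- function(name, weight, high = character(),
                            log_mean_low = log(50), log_mean_high = log(5000),
                            log_sd = 0.35, activation_shift = numeric()) {
  stopifnot(weight >= 0, log_sd > 0)
  structure(
    list(
      name = name, weight = weight, high = high,
      log_mean_low = log_mean_low, log_mean_high = log_mean_high,
      log_sd = log_sd, activation_shift = activation_shift
    ),
    class = "population_spec"
  )
}

#' Default synthetic population mixture
#'
#' Eight populations spanning the functional T cell landscape the panel
#' resolves: naive and activated CD4 subsets, an exhausted CD4 subset, four
#' CD8 effector subsets mirroring the response-associated phenotypes
#' (cytotoxic GrzB+CD26+; activated BCL-2+CD26+CD154+; infiltrating
#' CD103+TIGIT+CD26+; resilient TIGIT+), and an unconventional CD4-CD8-
#' CCR6+CD137+ subset. Locations are separated by several log-SD so mixture
#' recovery by clustering is well-posed; stimulated-condition shifts act on
#' activation markers (CD137, IFN-g, TNF-a, IL-2, CD154, HLA-DR).
#'
#' @return List of [population_spec()] objects.
#' @export
default_populations <- function() {
  act <- c("CD137" = 1.2, "IFN-g" = 1.5, "TNF-a" = 1.2, "IL-2" = 1.0,
           "CD154" = 0.8, "HLA-DR" = 0.6)
  list(
    population_spec("cd4_naive", 0.20,
                    high = c("CD3", "CD4", "CD45RA", "CCR7")),
    population_spec("cd4_activated", 0.12,
                    high = c("CD3", "CD4", "CD25", "HLA-DR", "CD154", "CD95"),
                    activation_shift = act),
    population_spec("cd4_exhausted", 0.10,
                    high = c("CD3", "CD4", "PD-1", "TIM-3", "LAG-3")),
    population_spec("cd8_cytotoxic", 0.15,
                    high = c("CD3", "CD8", "GrzB", "CD26"),
                    activation_shift = act),
    population_spec("cd8_activated", 0.13,
                    high = c("CD3", "CD8", "BCL-2", "CD26", "CD154"),
                    activation_shift = act),
    population_spec("cd8_infiltrating", 0.12,
                    high = c("CD3", "CD8", "CD103", "TIGIT", "CD26")),
    population_spec("cd8_resilient", 0.10,
                    high = c("CD3", "CD8", "TIGIT", "BCL-2")),
    population_spec("dn_unconventional", 0.08,
                    high = c("CD3", "CCR6", "CD137", "IL-22"))
  )
}

#' Configure a synthetic product cohort
#'
#' Describes the cohort the generators emulate: products (donors) carrying a
#' group tag (`GD2` for CAR-only, `C7R` for CAR+C7R co-expression) and an
#' ordinal clinical outcome (`PD` < `SD` < `PR`, encoded 0/1/2), the two
#' culture conditions, the number of events per sample, and the transduction
#' fractions. Defaults mirror a ten-product cohort (three CAR-only, seven
#' co-expressing C7R; one PR, four SD, five PD) with mean CAR positivity
#' 56.71% and CAR+C7R co-expression 23.07%.
#'
#' @param n_donors Number of products.
#' @param groups Character vector (`"GD2"`/`"C7R"`), recycled to `n_donors`.
#' @param outcomes Ordinal outcomes (`"PD"`, `"SD"`, `"PR"`).
#' @param conditions Culture conditions simulated per product.
#' @param events_per_sample Events per (donor, condition) sample (> 0).
#' @param car_positive_fraction,c7r_positive_fraction Transduction
#'   probabilities in \[0, 1\]; the C7R fraction applies to C7R-group
#'   products only.
#' @param seed Integer seed; same seed gives bit-identical cohorts.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_donors = 10,
                          groups = c(rep("GD2", 3), rep("C7R", 7)),
                          outcomes = c("PD", "PD", "PD",
                                       "PD", "PD", "SD", "SD", "SD", "SD", "PR"),
                          conditions = c("unstim", "stim"),
                          events_per_sample = 5000,
                          car_positive_fraction = 0.5671,
                          c7r_positive_fraction = 0.2307,
                          seed = 1L) {
  stopifnot(
    n_donors >= 0, events_per_sample > 0,
    car_positive_fraction >= 0, car_positive_fraction <= 1,
    c7r_positive_fraction >= 0, c7r_positive_fraction <= 1
  )
  groups <- rep_len(groups, max(n_donors, 1L))[seq_len(n_donors)]
  outcomes <- rep_len(outcomes, max(n_donors, 1L))[seq_len(n_donors)]
  stopifnot(all(outcomes %in% c("PD", "SD", "PR")))
  structure(
    list(
      donors = if (n_donors > 0) sprintf("prod%02d", seq_len(n_donors)) else character(),
      groups = groups, outcomes = outcomes, conditions = conditions,
      events_per_sample = as.integer(events_per_sample),
      car_positive_fraction = car_positive_fraction,
      c7r_positive_fraction = c7r_positive_fraction,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Encode ordinal clinical outcomes
#'
#' Immunotherapy response categories ordered progressive disease < stable
#' disease < partial response, encoded 0 < 1 < 2.
#'
#' @param outcomes Character vector of `"PD"`, `"SD"`, `"PR"`.
#' @return Integer vector.
#' @export
outcome_rank <- function(outcomes) {
  unname(c(PD = 0L, SD = 1L, PR = 2L)[outcomes])
}
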