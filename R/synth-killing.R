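#' Parameters of the serial killing-assay generator
#'
#' Describes an 11-round, 33-day serial re-challenge co-culture imaged every
#' 7 hours. At the start of each round the tumor GFP area resets to `area0`
#' (fresh tumor cells added); within a round the area evolves exponentially
#' with net rate (growth − effective kill), where
#' `effective_kill = kill_rate * et_scaling[ratio] * round_decay^(round-1)`.
#' `round_decay < 1` models progressive loss of effector potency over
#' re-challenge rounds.
#'
#' @param area0 Initial GFP area per round (a.u., > 0).
#' @param growth_rate Tumor growth rate per hour.
#' @param kill_rate Product elimination rate per hour at the reference 2:1
#'   effector-to-target ratio; may be `Inf` for instantaneous clearance.
#' @param et_scaling Named multipliers per E:T ratio.
#' @param round_decay Multiplicative potency retention per round, in (0, 1].
#' @param rounds Number of re-challenge rounds.
#' @param frames_per_round Frames per round, anchor frame included.
#' @param frame_interval_h Hours between frames.
#' @param noise_sd Optional log-normal area noise (SD on the log scale; 0 =
#'   noise-free).
#' @return A `killing_params` list.
#' @export
killing_params <- function(area0 = 1e5, growth_rate = 0.02, kill_rate = 0.05,
                           et_scaling = c("2:1" = 1, "1:1" = 0.6,
                                          "1:2" = 0.35, "1:6" = 0.15),
                           round_decay = 0.9, rounds = 11,
                           frames_per_round = 11, frame_interval_h = 7,
                           noise_sd = 0) {
  if (!is.finite(area0) || area0 <= 0) {
    abort("`area0` must be a positive finite number.")
  }
  stopifnot(rounds >= 1, frame_interval_h > 0,
            round_decay > 0, round_decay <= 1,
            frames_per_round >= 1, noise_sd >= 0)
  structure(
    list(area0 = area0, growth_rate = growth_rate, kill_rate = kill_rate,
         et_scaling = et_scaling, round_decay = round_decay,
         rounds = as.integer(rounds),
         frames_per_round = as.integer(frames_per_round),
         frame_interval_h = frame_interval_h, noise_sd = noise_sd),
    class = "killing_params"
  )
}

#' Simulate a serial killing-assay GFP-area series
#'
#' Generates the long-format area table the killing-assay stage consumes:
#' one row per (product, E:T ratio, round, frame). Hours restart at 0 at each
#' round's anchor frame (re-challenge reset).
#'
#' @param params A [killing_params()].
#' @param et_ratios E:T ratios to simulate; must name entries of
#'   `params$et_scaling`.
#' @param product Product label.
#' @param seed Seed for the optional log-normal noise.
#' @return Tibble with columns `product`, `et_ratio`, `round`, `hours`,
#'   `area`.
#' @export
#' @examples
#' ks <- simulate_killing_series(killing_params(kill_rate = 0.08))
#' head(ks)
simulate_killing_series <- function(params,
                                    et_ratios = names(params$et_scaling),
                                    product = "prod01", seed = 1L) {
  if (length(et_ratios) == 0) abort("`et_ratios` must be non-empty.")
  missing_et <- setdiff(et_ratios, names(params$et_scaling))
  if (length(missing_et)) {
    abort(paste0("No et_scaling entry for ratio(s): ",
                 paste(missing_et, collapse = ", ")))
  }
  hours <- (seq_len(params$frames_per_round) - 1L) * params$frame_interval_h
  grid <- tidyr::expand_grid(
    product = product,
    et_ratio = et_ratios,
    round = seq_len(params$rounds),
    hours = hours
  )
  eff_kill <- params$kill_rate * params$et_scaling[grid$et_ratio] *
    params$round_decay^(grid$round - 1)
  net <- params$growth_rate - eff_kill
  # exp(-Inf * 0) at the anchor frame must stay area0; post-anchor -> 0.
  logfac <- ifelse(grid$hours == 0, 0, net * grid$hours)
  area <- params$area0 * exp(logfac)
  if (params$noise_sd > 0) {
    withr::with_seed(seed, {
      noise <- rlnorm(nrow(grid), 0, params$noise_sd)
    })
    area <- area * noise
  }
  dplyr::mutate(grid, area = unname(area))
}
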