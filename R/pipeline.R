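#' Default pipeline configuration
#'
#' Nested list of every stage parameter with the study-pipeline defaults:
#' arcsinh cofactor 150; drift-cleaner segment size 500 with a 0.3 removal
#' cap; 100,000-event subsample cap; SOM 10 x 10 grid, 10 epochs, seed 3421;
#' metacluster count; presence threshold 0.58; E:T ratios 2:1/1:1/1:2/1:6
#' with the 2:1 ratio feeding the scorecard; fixed radar axis order. Stage
#' toggles allow partial runs; disabling a stage a later stage depends on
#' fails fast with a stage-named error.
#'
#' @param n_donors,events_per_sample Synthetic cohort size.
#' @param k Metacluster count.
#' @return Named list; edit fields or supply your own YAML via
#'   [run_pipeline()].
#' @export
default_run_config <- function(n_donors = 10, events_per_sample = 2000,
                               k = 8) {
  list(
    stages = list(simulate = TRUE, preprocess = TRUE, cluster = TRUE,
                  killing = TRUE, scorecard = TRUE, associate = TRUE,
                  qc = TRUE),
    cohort = list(n_donors = n_donors, events_per_sample = events_per_sample),
    preprocess = list(cofactor = 150, segment_size = 500,
                      max_removed_fraction = 0.3, subsample_cap = 100000),
    cluster = list(xdim = 10, ydim = 10, rlen = 10, som_seed = 3421, k = k),
    profile = list(threshold = 0.58),
    killing = list(et_ratios = c("2:1", "1:1", "1:2", "1:6"),
                   scorecard_ratio = "2:1", rounds = 11,
                   frames_per_round = 11, frame_interval_h = 7,
                   growth_rate = 0.02, base_kill_rate = 0.035,
                   kill_step = 0.004, c7r_bonus = 0.02, round_decay = 0.92,
                   noise_sd = 0),
    scorecard = list(axes = c("cytotoxicity", "activation", "infiltration",
                              "resilience", "iv33"),
                     floor = 0.05),
    gating = list(positivity_quantile_midpoint = 500)
  )
}

#' Run the profiling pipeline end to end
#'
#' Orchestrates simulate -> preprocess -> cluster -> killing -> scorecard ->
#' associate -> qc from one configuration, with every stage seed derived
#' deterministically from the global seed. Stage outputs are written as
#' CSV/JSON under `outdir` together with a manifest (package version, seeds,
#' parameter echo, per-file MD5 checksums); reruns with the same seed and
#' config are bit-identical.
#'
#' @param config Configuration list ([default_run_config()]) or a YAML file
#'   path with the same structure.
#' @param seed Global integer seed.
#' @param outdir Output directory (created if needed); `NULL` skips writing.
#' @return Invisible list of all stage results plus `$manifest`.
#' @export
run_pipeline <- function(config = default_run_config(), seed = 1L,
                         outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(default_run_config(), config)
  on <- cfg$stages
  res <- list()

  need <- function(stage, dep, have) {
    if (!have) {
      abort(paste0("Stage '", stage, "' requires stage '", dep,
                   "' to be enabled."))
    }
  }

  # -- simulate ------------------------------------------------------------
  if (isTRUE(on$simulate)) {
    cohort <- cohort_config(
      n_donors = cfg$cohort$n_donors,
      events_per_sample = cfg$cohort$events_per_sample,
      seed = derive_seed(seed, 1L)
    )
    events <- simulate_event_tables(cohort)
    kp <- cfg$killing
    kill_rates <- kp$base_kill_rate + kp$kill_step * seq_along(cohort$donors) +
      ifelse(cohort$groups == "C7R", kp$c7r_bonus, 0)
    killing <- purrr::map2_dfr(cohort$donors, kill_rates, function(d, kr) {
      simulate_killing_series(
        killing_params(growth_rate = kp$growth_rate, kill_rate = kr,
                       round_decay = kp$round_decay, rounds = kp$rounds,
                       frames_per_round = kp$frames_per_round,
                       frame_interval_h = kp$frame_interval_h,
                       noise_sd = kp$noise_sd),
        et_ratios = kp$et_ratios, product = d,
        seed = derive_seed(seed, 2L)
      )
    })
    correlates <- simulate_correlates(cohort, seed = derive_seed(seed, 3L))
    res$simulate <- list(cohort = cohort, events = events,
                         killing = killing, correlates = correlates)
  }

  # -- preprocess ----------------------------------------------------------
  if (isTRUE(on$preprocess)) {
    need("preprocess", "simulate", !is.null(res$simulate))
    pp <- cfg$preprocess
    ev <- transform_arcsinh(res$simulate$events, cofactors = pp$cofactor)
    tree <- gate_tree(
      gate_node("viable", "all", "Viability",
                upper = asinh(100 / pp$cofactor)),
      gate_node("T cells", "viable", "CD3",
                lower = asinh(500 / pp$cofactor))
    )
    gated <- apply_gates(ev, tree, "T cells")
    cleaned <- clean_time_drift(gated, segment_size = pp$segment_size,
                                max_removed_fraction = pp$max_removed_fraction)
    sub <- cleaned$events |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::group_split() |>
      purrr::imap(function(s, i) {
        subsample_events(s, cap = pp$subsample_cap,
                         seed = derive_seed(seed, 10L + i))
      }) |>
      dplyr::bind_rows()
    sub <- set_event_attrs(sub, markers = event_markers(ev),
                           state = "arcsinh")
    res$preprocess <- list(events = sub, gate_tree = tree,
                           cleaning_report = cleaned$report)
  }

  # -- cluster -------------------------------------------------------------
  if (isTRUE(on$cluster)) {
    need("cluster", "preprocess", !is.null(res$preprocess))
    cl <- cfg$cluster
    ev <- res$preprocess$events
    fit <- fit_som(ev, xdim = cl$xdim, ydim = cl$ydim, rlen = cl$rlen,
                   seed = cl$som_seed)
    mc <- event_metaclusters(fit, k = cl$k)
    meta <- dplyr::distinct(ev[, c("sample_id", "donor", "condition",
                                   "product_group", "outcome")])
    ab <- cluster_abundance(mc, ev$sample_id, sample_meta = meta)
    profile <- profile_clusters(ev, mc, threshold = cfg$profile$threshold)
    delta <- delta_mean_abundance(ab)
    assoc <- outcome_association(
      ab[ab$condition == "stim", , drop = FALSE]
    )
    res$cluster <- list(som = fit, metaclusters = mc, abundance = ab,
                        profile = profile, delta = delta,
                        outcome_association = assoc)
  }

  # -- killing -------------------------------------------------------------
  if (isTRUE(on$killing)) {
    need("killing", "simulate", !is.null(res$simulate))
    pct <- percent_killing(res$simulate$killing)
    iv3 <- killing_iv3(pct)
    iv33 <- killing_iv33(iv3, expected_rounds = cfg$killing$rounds)
    res$killing <- list(pct = pct, iv3 = iv3, iv33 = iv33)
  }

  # -- scorecard -----------------------------------------------------------
  if (isTRUE(on$scorecard)) {
    need("scorecard", "preprocess", !is.null(res$preprocess))
    need("scorecard", "killing", !is.null(res$killing))
    pp <- cfg$preprocess
    ev <- res$preprocess$events
    # Positivity thresholds: geometric midpoint of the bimodal raw scale.
    mid <- asinh(cfg$gating$positivity_quantile_midpoint / pp$cofactor)
    thresholds <- setNames(rep(mid, length(event_markers(ev))),
                           event_markers(ev))
    cd8 <- ev[ev$CD8 >= mid & ev$condition == "stim", , drop = FALSE]
    sigs <- default_signatures()
    freqs <- cd8 |>
      dplyr::group_by(.data$donor, .data$product_group) |>
      dplyr::group_modify(function(d, key) {
        vals <- purrr::map_dbl(sigs, function(s) {
          signature_frequency(d, s, thresholds)
        })
        as_tibble(as.list(vals))
      }) |>
      dplyr::ungroup() |>
      dplyr::rename(product = "donor")
    iv_card <- res$killing$iv33 |>
      dplyr::filter(.data$et_ratio == cfg$killing$scorecard_ratio) |>
      dplyr::select("product", "iv33")
    metrics <- dplyr::inner_join(freqs, iv_card, by = "product")
    cards <- build_scorecards(metrics, axes = cfg$scorecard$axes,
                              floor = cfg$scorecard$floor)
    res$scorecard <- list(metrics = metrics, cards = cards,
                          group_summary = scorecard_group_summary(cards))
  }

  # -- associate -----------------------------------------------------------
  if (isTRUE(on$associate)) {
    need("associate", "simulate", !is.null(res$simulate))
    cs <- res$simulate$correlates
    scores <- cytokine_group_scores(cs)
    deltas <- timepoint_deltas(scores)
    rho <- spearman_assoc(cs$metrics, deltas)
    aucs <- persistence_auc_by_patient(cs)
    reg <- NULL
    if (!is.null(res$scorecard)) {
      joined <- dplyr::inner_join(
        tibble(patient = res$scorecard$cards$product,
               area = res$scorecard$cards$area),
        aucs, by = "patient"
      )
      reg <- pearson_regression(joined$area, joined$auc)
    }
    res$associate <- list(scores = scores, deltas = deltas, spearman = rho,
                          persistence_auc = aucs, regression = reg)
  }

  # -- qc ------------------------------------------------------------------
  if (isTRUE(on$qc)) {
    withr::with_seed(derive_seed(seed, 4L), {
      dil <- c("1:50", "1:100", "1:200", "1:400")
      sep <- c(6, 10, 8, 5)   # planted optimum at 1:100
      titr <- tibble(
        dilution = dil,
        mfi_positive = 100 + 2 * 45 * sep + rnorm(4, 0, 10),
        mfi_negative = 100, sd_negative = 45
      )
      fmo <- tidyr::expand_grid(marker = default_panel()[1:6],
                                donor = c("d1", "d2", "d3")) |>
        dplyr::mutate(frequency = 15 + rnorm(dplyr::n(), 0, 2))
    })
    res$qc <- list(
      titration = titr,
      best_dilution = select_titration(titr),
      fmo = fmo_variability(fmo)
    )
  }

  res$manifest <- write_pipeline_outputs(res, cfg, seed, outdir)
  invisible(res)
}

# Serialise stage outputs and build the run manifest.
write_pipeline_outputs <- function(res, cfg, seed, outdir) {
  files <- character()
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    emit_csv <- function(x, name) {
      p <- file.path(outdir, name)
      write.csv(x, p, row.names = FALSE)
      files[[name]] <<- p
    }
    emit_json <- function(x, name) {
      p <- file.path(outdir, name)
      jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      files[[name]] <<- p
    }
    if (!is.null(res$preprocess)) {
      emit_csv(res$preprocess$cleaning_report, "cleaning_report.csv")
    }
    if (!is.null(res$cluster)) {
      emit_csv(res$cluster$abundance, "cluster_abundance.csv")
      d <- res$cluster$delta
      d$convention <- attr(res$cluster$delta, "convention")
      emit_csv(d, "delta_mean_abundance.csv")
      emit_csv(res$cluster$outcome_association, "outcome_association.csv")
      emit_csv(tidy(res$cluster$profile), "cluster_profile.csv")
    }
    if (!is.null(res$killing)) {
      emit_csv(res$killing$iv3, "killing_iv3.csv")
      emit_csv(res$killing$iv33, "killing_iv33.csv")
    }
    if (!is.null(res$scorecard)) {
      emit_csv(tidy(res$scorecard$cards), "scorecards.csv")
      emit_csv(res$scorecard$group_summary, "scorecard_group_summary.csv")
    }
    if (!is.null(res$associate)) {
      emit_csv(res$associate$spearman, "spearman_associations.csv")
      emit_csv(res$associate$persistence_auc, "persistence_auc.csv")
      if (!is.null(res$associate$regression)) {
        emit_json(res$associate$regression, "persistence_regression.json")
      }
    }
    if (!is.null(res$qc)) {
      emit_json(res$qc[c("best_dilution", "fmo")], "panel_qc.json")
    }
  }
  manifest <- list(
    package = "cartprofiler",
    version = as.character(utils::packageVersion("cartprofiler")),
    seed = seed,
    stages_run = names(Filter(isTRUE, cfg$stages)),
    parameters = cfg,
    checksums = if (length(files)) {
      as.list(setNames(tools::md5sum(unname(unlist(files))), names(files)))
    } else list()
  )
  if (!is.null(outdir)) {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  manifest
}
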