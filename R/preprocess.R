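#' Arcsinh-transform marker intensities
#'
#' Applies the variance-stabilising scaling `asinh(x / cofactor)` per
#' channel: approximately linear near zero and logarithmic for bright
#' signal, monotone and odd. The conventional flow-cytometry cofactor 150 is
#' the default for every channel; supply a named vector to override per
#' channel.
#'
#' @param events Event table with `scale_state = "raw"`.
#' @param cofactors Single positive number or named per-channel vector.
#' @return Event table with transformed markers and
#'   `scale_state = "arcsinh"`.
#' @export
#' @examples
#' ev <- simulate_event_tables(cohort_config(n_donors = 1, events_per_sample = 100))
#' tr <- transform_arcsinh(ev)
#' scale_state(tr)
transform_arcsinh <- function(events, cofactors = 150) {
  if (scale_state(events) != "raw") {
    abort("Events are already transformed (scale_state != 'raw').")
  }
  markers <- event_markers(events)
  cf <- if (length(cofactors) == 1 && is.null(names(cofactors))) {
    setNames(rep(cofactors, length(markers)), markers)
  } else {
    missing_cf <- setdiff(markers, names(cofactors))
    if (length(missing_cf)) {
      abort(paste0("No cofactor for channel(s): ",
                   paste(missing_cf, collapse = ", ")))
    }
    cofactors[markers]
  }
  if (any(!is.finite(cf)) || any(cf <= 0)) {
    abort("All cofactors must be positive and finite.")
  }
  for (m in markers) events[[m]] <- asinh(events[[m]] / cf[[m]])
  set_event_attrs(events, markers = markers, state = "arcsinh")
}

#' Remove acquisition-drift segments
#'
#' A simplified signal-drift cleaner: events are ordered by the acquisition
#' `time` channel and split into consecutive segments of `segment_size`;
#' each channel's segment means are standardised robustly (median and MAD
#' across segments), and a segment is flagged when any channel deviates by
#' more than `z_threshold` robust SDs. Flagged segments are removed
#' worst-first, capped at `max_removed_fraction` of segments. A global shift
#' common to all segments produces no flags (the statistic is relative).
#' The default threshold of 7 follows the removal multiplier conventional
#' for flow-cytometry drift cleaning; with robust scaling it keeps the
#' false-flag rate on stationary data negligible while genuine multi-SD
#' drift stands out by an order of magnitude. This is a deliberately simple
#' segment-mean outlier rule, not a full valley/continuity cleaning
#' algorithm.
#'
#' @param events Event table carrying a `time` column.
#' @param segment_size Events per segment.
#' @param max_removed_fraction Cap on the fraction of segments removed.
#' @param z_threshold Flagging threshold on the robust segment-mean z-score.
#' @return List with `$events` (cleaned table) and `$report` (a tibble:
#'   segments examined/removed, events removed, and the worst per-channel
#'   drift z).
#' @export
clean_time_drift <- function(events, segment_size = 500,
                             max_removed_fraction = 0.3, z_threshold = 7) {
  if (!"time" %in% names(events)) {
    warn("No acquisition-time channel; drift cleaning skipped.")
    report <- tibble(segments_examined = 0L, segments_removed = 0L,
                     events_removed = 0L, max_abs_z = NA_real_)
    return(list(events = events, report = report))
  }
  ord <- order(events$time)
  n <- nrow(events)
  n_seg <- max(1L, floor(n / segment_size))
  seg_of <- pmin(ceiling(seq_len(n) / segment_size), n_seg)

  markers <- event_markers(events)
  mat <- marker_matrix(events[ord, , drop = FALSE], markers)
  seg_means <- rowsum(mat, seg_of) / as.vector(table(seg_of))
  mu <- apply(seg_means, 2, median)
  s <- apply(seg_means, 2, mad)
  s0 <- apply(seg_means, 2, sd)              # fallback when MAD degenerates
  s[!is.finite(s) | s == 0] <- s0[!is.finite(s) | s == 0]
  s[!is.finite(s) | s == 0] <- Inf           # constant channel: never flags
  z <- sweep(sweep(seg_means, 2, mu), 2, s, "/")
  worst <- apply(abs(z), 1, max)

  flagged <- which(worst > z_threshold)
  cap <- floor(max_removed_fraction * n_seg)
  if (length(flagged) > cap) {
    flagged <- flagged[order(worst[flagged], decreasing = TRUE)][seq_len(cap)]
  }
  drop_rows <- ord[seg_of %in% flagged]
  out <- if (length(drop_rows)) events[-drop_rows, , drop = FALSE] else events
  report <- tibble(
    segments_examined = n_seg,
    segments_removed = length(flagged),
    events_removed = length(drop_rows),
    max_abs_z = max(worst)
  )
  list(events = set_event_attrs(out, markers = markers,
                                state = scale_state(events)),
       report = report)
}

#' Subsample events to a per-sample cap
#'
#' Uniform random subsampling without replacement to at most `cap` events,
#' the standardisation step that prevents donor bias in pooled
#' high-dimensional analyses. Tables at or under the cap are returned
#' unchanged; the draw is seeded and reproducible.
#'
#' @param events Event table (one sample; apply per group for cohorts).
#' @param cap Maximum events retained (default 100,000).
#' @param seed Integer seed.
#' @return Event table with `min(n, cap)` rows.
#' @export
subsample_events <- function(events, cap = 100000, seed = 1L) {
  stopifnot(cap > 0)
  n <- nrow(events)
  if (n <= cap) return(events)
  withr::with_seed(seed, {
    keep <- sort(sample.int(n, cap))
  })
  out <- events[keep, , drop = FALSE]
  set_event_attrs(out, markers = event_markers(events),
                  state = scale_state(events))
}
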