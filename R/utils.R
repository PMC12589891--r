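# Internal helpers shared across modules.

# Metadata columns an event table may carry alongside marker channels.
.meta_cols <- c(
  "sample_id", "donor", "condition", "product_group", "outcome",
  "car_pos", "c7r_pos", ".population", "time"
)

#' Marker channels of an event table
#'
#' Event tables carry sample metadata (donor, condition, product group,
#' outcome, acquisition time, hidden ground-truth labels) next to the marker
#' intensity columns. `event_markers()` returns the marker column names; the
#' set is recorded in the `markers` attribute when the table is created and
#' falls back to "every non-metadata column" otherwise.
#'
#' @param events An event table (tibble, one row per event).
#' @return Character vector of marker column names.
#' @export
event_markers <- function(events) {
  m <- attr(events, "markers", exact = TRUE)
  if (!is.null(m)) {
    return(intersect(m, names(events)))
  }
  setdiff(names(events), .meta_cols)
}

#' Scale state of an event table
#'
#' Tracks whether marker intensities are raw or arcsinh-transformed. Tables
#' produced by the package always carry the state; absent the attribute,
#' intensities are assumed raw.
#'
#' @param events An event table.
#' @return `"raw"` or `"arcsinh"`.
#' @export
scale_state <- function(events) {
  attr(events, "scale_state", exact = TRUE) %||% "raw"
}

`scale_state<-` <- function(events, value) {
  attr(events, "scale_state") <- value
  events
}

set_event_attrs <- function(events, markers = NULL, state = NULL) {
  if (!is.null(markers)) attr(events, "markers") <- markers
  if (!is.null(state)) attr(events, "scale_state") <- state
  events
}

# Deterministic child seed from a global seed; kept well below 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(offset)
}

# Marker matrix (events x channels) from an event table.
marker_matrix <- function(events, markers = event_markers(events)) {
  as.matrix(events[, markers, drop = FALSE])
}
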