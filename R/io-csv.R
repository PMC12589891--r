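#' Read cytometry events
#'
#' Reads an event table from disk. `dialect = "csv"` expects one row per
#' event with a header row of channel names (UTF-8, comma-separated) and
#' optionally a YAML sidecar (`<path>.meta.yaml` or via `meta`) carrying
#' sample metadata and the marker list; `dialect = "fcs"` reads FCS 3.0/3.1
#' files with float data (see [read_fcs()]). The returned table has
#' `scale_state = "raw"`.
#'
#' @param path Input file.
#' @param dialect `"csv"` or `"fcs"`.
#' @param meta Optional path to a YAML metadata sidecar (CSV dialect).
#' @param panel Optional expected channel names; channels outside the panel
#'   trigger a warning but are passed through.
#' @return An event table tibble.
#' @export
read_events <- function(path, dialect = c("csv", "fcs"), meta = NULL,
                        panel = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (dialect == "fcs") {
    out <- read_fcs(path)
  } else {
    df <- as_tibble(read.csv(path, check.names = FALSE))
    if (anyNA(df)) abort("Event CSV contains missing values.")
    markers <- setdiff(names(df), .meta_cols)
    side <- meta %||% paste0(path, ".meta.yaml")
    if (file.exists(side)) {
      m <- yaml::read_yaml(side)
      for (field in intersect(names(m), .meta_cols)) {
        df[[field]] <- m[[field]]
      }
      if (!is.null(m$markers)) markers <- intersect(m$markers, names(df))
    }
    out <- set_event_attrs(df, markers = markers, state = "raw")
  }
  if (!is.null(panel)) {
    unknown <- setdiff(event_markers(out), panel)
    if (length(unknown)) {
      warn(paste0("Channels not in the configured panel (passed through): ",
                  paste(unknown, collapse = ", ")))
    }
  }
  out
}

#' Write cytometry events
#'
#' CSV dialect writes the marker channels (plus `time` if present) with a
#' header row, and the sample metadata to a YAML sidecar `<path>.meta.yaml`.
#' FCS dialect writes a minimal FCS 3.1 file ([write_fcs()]).
#'
#' @param events An event table.
#' @param path Output file.
#' @param dialect `"csv"` or `"fcs"`.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, dialect = c("csv", "fcs")) {
  dialect <- match.arg(dialect)
  markers <- event_markers(events)
  if (dialect == "fcs") {
    write_fcs(events, path)
    return(invisible(path))
  }
  cols <- c(intersect("time", names(events)), markers)
  write.csv(events[, cols, drop = FALSE], path, row.names = FALSE)
  meta_fields <- intersect(setdiff(.meta_cols, "time"), names(events))
  m <- lapply(events[meta_fields], function(v) {
    u <- unique(v)
    if (length(u) == 1) u else v
  })
  m$markers <- markers
  m$scale_state <- scale_state(events)
  yaml::write_yaml(m, paste0(path, ".meta.yaml"))
  invisible(path)
}
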