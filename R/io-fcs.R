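# Minimal FCS 3.1 codec: list-mode, 32-bit float data, one data segment.
# Covers the files this package writes plus plain float FCS 3.0/3.1 exports;
# it is deliberately not a general replacement for a full cytometry IO stack
# (no integer data types, no bit masks, no multi-dataset files).

#' Read a minimal FCS 3.0/3.1 file
#'
#' Parses the header, TEXT segment and a single list-mode DATA segment of
#' 32-bit floats (`$DATATYPE F`, `$PnB 32`, little- or big-endian
#' `$BYTEORD`). Channel names come from `$PnN`.
#'
#' @param path FCS file path.
#' @return Event table tibble (`scale_state = "raw"`).
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- rawToChar(readBin(con, "raw", 58))
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    abort(paste0("Unsupported FCS version or malformed file: ", version))
  }
  off <- function(i) {
    as.numeric(trimws(substr(header, 11 + (i - 1) * 8, 10 + i * 8)))
  }
  text_beg <- off(1); text_end <- off(2)
  data_beg <- off(3); data_end <- off(4)

  seek(con, text_beg)
  text_raw <- readBin(con, "raw", text_end - text_beg + 1)
  text <- rawToChar(text_raw)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- setNames(parts[seq(2, length(parts), 2)],
                 toupper(trimws(parts[seq(1, length(parts), 2)])))

  n_par <- as.integer(kw[["$PAR"]])
  n_tot <- as.integer(kw[["$TOT"]])
  if (!identical(kw[["$DATATYPE"]], "F")) {
    abort("Only $DATATYPE F (32-bit float) FCS data is supported.")
  }
  if (data_beg == 0 && !is.null(kw[["$BEGINDATA"]])) {
    data_beg <- as.numeric(kw[["$BEGINDATA"]])
    data_end <- as.numeric(kw[["$ENDDATA"]])
  }
  endian <- if (identical(kw[["$BYTEORD"]], "4,3,2,1")) "big" else "little"

  seek(con, data_beg)
  vals <- readBin(con, "double", n = n_par * n_tot, size = 4, endian = endian)
  mat <- matrix(vals, nrow = n_tot, ncol = n_par, byrow = TRUE)
  colnames(mat) <- vapply(seq_len(n_par), function(i) {
    kw[[paste0("$P", i, "N")]] %||% paste0("ch", i)
  }, character(1))
  out <- as_tibble(mat)
  markers <- setdiff(colnames(mat), "time")
  set_event_attrs(out, markers = markers, state = "raw")
}

#' Write a minimal FCS 3.1 file
#'
#' Writes the marker channels (plus `time` if present) as little-endian
#' 32-bit floats in list mode. Values round-trip at single precision.
#'
#' @param events An event table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(events, path) {
  cols <- c(intersect("time", names(events)), event_markers(events))
  mat <- as.matrix(events[, cols, drop = FALSE])
  storage.mode(mat) <- "double"
  n_tot <- nrow(mat); n_par <- ncol(mat)

  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(n_par), "$TOT" = as.character(n_tot)
  )
  for (i in seq_len(n_par)) {
    kw[paste0("$P", i, "N")] <- cols[i]
    kw[paste0("$P", i, "B")] <- "32"
    kw[paste0("$P", i, "E")] <- "0,0"
    kw[paste0("$P", i, "R")] <- format(max(1, ceiling(max(mat[, i], 0))),
                                       scientific = FALSE)
  }
  # Fixed-width data offsets keep the TEXT length stable while we compute it.
  kw["$BEGINDATA"] <- "0000000000"
  kw["$ENDDATA"] <- "0000000000"
  build_text <- function(kw) {
    paste0("/", paste0(names(kw), "/", unname(kw), collapse = "/"), "/")
  }
  text_beg <- 58L
  text <- build_text(kw)
  data_beg <- text_beg + nchar(text, type = "bytes")
  data_end <- data_beg + 4L * n_par * n_tot - 1L
  kw["$BEGINDATA"] <- sprintf("%010d", data_beg)
  kw["$ENDDATA"] <- sprintf("%010d", data_end)
  text <- build_text(kw)
  text_end <- text_beg + nchar(text, type = "bytes") - 1L

  fmt8 <- function(x) {
    s <- if (x > 99999999) "0" else as.character(x)
    formatC(s, width = 8)
  }
  header <- paste0(
    "FCS3.1    ",
    fmt8(text_beg), fmt8(text_end),
    if (data_end > 99999999) paste0(fmt8(0), fmt8(0)) else paste0(fmt8(data_beg), fmt8(data_end)),
    fmt8(0), fmt8(0)
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(text), con)
  writeBin(as.vector(t(mat)), con, size = 4, endian = "little")
  invisible(path)
}
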