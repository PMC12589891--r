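#' Two-dimensional neighbor embedding of events
#'
#' Uniform manifold approximation (UMAP) of the event x marker matrix,
#' delegated to the established `umap-learn` implementation driven through a
#' Python subprocess; parameters follow the study pipeline defaults
#' (15 neighbors, minimum distance 0.4, Euclidean metric, spectral
#' initialisation, fixed random seed), and the embedding is deterministic
#' for a fixed seed. Coordinates are used for visualisation and may be
#' appended as clustering features (`umap-1`, `umap-2`).
#'
#' @param x Numeric matrix (events x channels) or an event table, in which
#'   case [clustering_markers()] selects the channels.
#' @param n_neighbors Neighborhood size (needs at least `n_neighbors + 1`
#'   events).
#' @param min_dist Minimum embedding distance.
#' @param seed Random seed passed to the embedder.
#' @param python Python interpreter with `umap-learn` installed.
#' @return Tibble with columns `umap_1`, `umap_2`, one row per event.
#' @export
embed_2d <- function(x, n_neighbors = 15, min_dist = 0.4, seed = 2553,
                     python = Sys.which("python")) {
  if (is.data.frame(x)) x <- marker_matrix(x, clustering_markers(x))
  x <- as.matrix(x)
  if (nrow(x) < n_neighbors + 1) {
    abort(paste0("At least n_neighbors + 1 = ", n_neighbors + 1,
                 " events are required."))
  }
  if (!nzchar(python)) abort("No python interpreter found for the embedding.")
  script <- system.file("python", "umap_embed.py", package = "cartprofiler")
  in_csv <- tempfile(fileext = ".csv")
  out_csv <- tempfile(fileext = ".csv")
  on.exit(unlink(c(in_csv, out_csv)), add = TRUE)
  write.table(x, in_csv, sep = ",", row.names = FALSE, col.names = FALSE)
  status <- system2(python,
                    c(script, in_csv, out_csv,
                      as.character(n_neighbors), as.character(min_dist),
                      as.character(seed)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(out_csv)) {
    abort("The neighbor-embedding subprocess failed.")
  }
  coords <- as.matrix(read.csv(out_csv, header = FALSE))
  tibble(umap_1 = coords[, 1], umap_2 = coords[, 2])
}
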