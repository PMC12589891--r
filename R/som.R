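#' Fit a self-organizing map to event intensities
#'
#' Batch-trained SOM on a rectangular `xdim` x `ydim` grid: `rlen` epochs in
#' which every event is assigned to its best-matching node (Euclidean
#' distance) and each node's codebook vector is updated to the
#' neighbourhood-weighted mean of its events, with a Gaussian neighbourhood
#' whose radius shrinks linearly over epochs. The final event assignment is
#' an exact nearest-codebook search, so assignments are reproducible and
#' independently checkable by brute force. The codebook is initialised from
#' a seeded random draw of events; nodes may end up empty (a warning is
#' issued when there are fewer events than nodes).
#'
#' @param x Numeric matrix (events x channels) or an event table, in which
#'   case [clustering_markers()] selects the channels (viability, CD3 and
#'   transgene-detection channels are never clustered on).
#' @param xdim,ydim Grid dimensions.
#' @param rlen Training epochs.
#' @param seed Integer seed.
#' @return A `som_fit` object: `$codebook` (nodes x channels), `$grid`
#'   (node coordinates), `$assignment` (node index per event), training
#'   parameters and the mean quantisation error.
#' @export
#' @examples
#' m <- matrix(rnorm(600), ncol = 3)
#' fit <- fit_som(m, xdim = 4, ydim = 4, rlen = 5, seed = 3421)
#' table(fit$assignment)
fit_som <- function(x, xdim = 10, ydim = 10, rlen = 10, seed = 3421) {
  if (is.data.frame(x)) x <- marker_matrix(x, clustering_markers(x))
  x <- as.matrix(x)
  if (nrow(x) < 1) abort("At least one event is required.")
  n_nodes <- xdim * ydim
  if (nrow(x) < n_nodes) {
    warn("Fewer events than SOM nodes; some nodes will be empty.")
  }
  grid <- as.matrix(expand.grid(gx = seq_len(xdim), gy = seq_len(ydim)))
  grid_d2 <- as.matrix(dist(grid))^2

  withr::with_seed(seed, {
    init_idx <- sample.int(nrow(x), n_nodes, replace = nrow(x) < n_nodes)
  })
  codebook <- x[init_idx, , drop = FALSE]
  radii <- seq(max(xdim, ydim) / 2, 0.5, length.out = rlen)

  for (ep in seq_len(rlen)) {
    bmu <- nearest_codebook(x, codebook)
    h <- exp(-grid_d2 / (2 * radii[ep]^2))     # nodes x nodes
    # Neighbourhood-weighted batch update: counts and sums per BMU node.
    counts <- tabulate(bmu, nbins = n_nodes)
    sums <- matrix(0, n_nodes, ncol(x))
    occ <- rowsum(x, bmu)
    sums[as.integer(rownames(occ)), ] <- occ
    denom <- as.vector(h %*% counts)
    num <- h %*% sums
    upd <- denom > 0
    codebook[upd, ] <- num[upd, , drop = FALSE] / denom[upd]
  }

  assignment <- nearest_codebook(x, codebook)
  d <- sqrt(rowSums((x - codebook[assignment, , drop = FALSE])^2))
  structure(
    list(codebook = codebook, grid = grid, assignment = assignment,
         xdim = xdim, ydim = ydim, rlen = rlen, seed = seed,
         n_events = nrow(x), quant_error = mean(d),
         channels = colnames(x)),
    class = "som_fit"
  )
}

# Exact nearest-codebook search (Euclidean), vectorised.
nearest_codebook <- function(x, codebook) {
  # ||x - c||^2 = ||x||^2 - 2 x.c + ||c||^2; row minimum over nodes.
  cross <- x %*% t(codebook)
  d2 <- sweep(-2 * cross, 2, rowSums(codebook^2), "+")
  max.col(-d2, ties.method = "first")
}

#' @export
print.som_fit <- function(x, ...) {
  cat("Self-organizing map:", x$xdim, "x", x$ydim, "grid,",
      x$n_events, "events,", x$rlen, "epochs\n")
  cat("Mean quantisation error:", format(x$quant_error, digits = 4), "\n")
  invisible(x)
}

#' @rdname fit_som
#' @param ... Unused.
#' @export
tidy.som_fit <- function(x, ...) {
  cb <- as_tibble(x$codebook)
  out <- dplyr::bind_cols(
    tibble(node = seq_len(nrow(cb)),
           grid_x = x$grid[, "gx"], grid_y = x$grid[, "gy"],
           n_events = tabulate(x$assignment, nbins = nrow(cb))),
    cb
  )
  tidyr::pivot_longer(out, -c("node", "grid_x", "grid_y", "n_events"),
                      names_to = "channel", values_to = "codebook_value")
}

#' @rdname fit_som
#' @export
glance.som_fit <- function(x, ...) {
  tibble(
    n_events = x$n_events, n_nodes = nrow(x$codebook),
    n_occupied = length(unique(x$assignment)),
    xdim = x$xdim, ydim = x$ydim, rlen = x$rlen, seed = x$seed,
    quant_error = x$quant_error
  )
}
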