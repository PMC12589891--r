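#' Consolidate SOM nodes into metaclusters
#'
#' Average-linkage hierarchical clustering of the occupied codebook vectors,
#' cut at `k` metaclusters (the automated counterpart of refining a SOM by
#' marker similarity and spanning-tree topology). Empty nodes are excluded
#' from the consolidation and map to `NA`.
#'
#' @param fit A [fit_som()] object.
#' @param k Target number of metaclusters, between 1 and the number of
#'   occupied nodes.
#' @return Integer vector mapping each node to a metacluster (`NA` for empty
#'   nodes); apply to events as `metacluster(fit, k)[fit$assignment]`.
#' @export
#' @examples
#' m <- rbind(matrix(rnorm(300), ncol = 3), matrix(rnorm(300, 8), ncol = 3))
#' fit <- fit_som(m, xdim = 4, ydim = 4, rlen = 5)
#' mc <- metacluster(fit, k = 2)
#' table(mc[fit$assignment])
metacluster <- function(fit, k) {
  occupied <- sort(unique(fit$assignment))
  if (k > length(occupied)) {
    abort(paste0("k = ", k, " exceeds the ", length(occupied),
                 " occupied SOM nodes."))
  }
  stopifnot(k >= 1)
  cb <- fit$codebook[occupied, , drop = FALSE]
  map <- rep(NA_integer_, nrow(fit$codebook))
  if (length(occupied) == 1) {
    map[occupied] <- 1L
    return(map)
  }
  hc <- hclust(dist(cb), method = "average")
  map[occupied] <- cutree(hc, k = k)
  map
}

#' Event-level metacluster assignments
#'
#' @param fit A [fit_som()] object.
#' @param k Number of metaclusters.
#' @return Integer metacluster per event.
#' @export
event_metaclusters <- function(fit, k) {
  metacluster(fit, k)[fit$assignment]
}

#' Per-sample cluster abundance table
#'
#' Percentage of each sample's events falling in each cluster; every row
#' sums to 100. Samples present in `sample_meta` but contributing no events
#' get a row of missing values.
#'
#' @param assignments Cluster label per event.
#' @param sample_ids Sample id per event.
#' @param sample_meta Optional tibble keyed by `sample_id` with grouping
#'   columns (e.g. `product_group`, `outcome`) to carry along.
#' @return Tibble, one row per sample: `sample_id`, metadata, one `cl_*`
#'   column per cluster.
#' @export
cluster_abundance <- function(assignments, sample_ids, sample_meta = NULL) {
  stopifnot(length(assignments) == length(sample_ids))
  keep <- !is.na(assignments)
  tab <- table(sample_ids[keep], assignments[keep])
  pct <- 100 * sweep(unclass(tab), 1, rowSums(tab), "/")
  colnames(pct) <- paste0("cl_", colnames(pct))
  out <- dplyr::bind_cols(tibble(sample_id = rownames(pct)), as_tibble(pct))
  if (!is.null(sample_meta)) {
    out <- dplyr::left_join(sample_meta, out, by = "sample_id")
  }
  out
}

abundance_cluster_cols <- function(tab) {
  grep("^cl_", names(tab), value = TRUE)
}

#' Profile clusters by marker intensity
#'
#' Builds the cluster x marker mean-intensity matrix, its min-max-scaled
#' twin (per marker, across clusters: `(MFI - min)/(max - min)`, with
#' constant markers mapped to 0 by convention), binary presence calls at a
#' scaled threshold, and average-linkage dendrogram orders for rows and
#' columns of the scaled matrix. The 0.58 presence threshold marks a marker
#' as expressed by a cluster when its scaled intensity reaches 58% of the
#' cross-cluster range.
#'
#' @param events Event table (or numeric matrix) on the scale to profile.
#' @param assignments Cluster label per event.
#' @param threshold Presence threshold on the scaled intensity.
#' @param markers Channels to profile; defaults to [clustering_markers()].
#' @return A `cluster_profile` object: `$mfi`, `$scaled`, `$present`
#'   (cluster x marker matrices), `$row_order`, `$col_order`, `$threshold`.
#' @export
profile_clusters <- function(events, assignments, threshold = 0.58,
                             markers = NULL) {
  if (is.data.frame(events)) {
    markers <- markers %||% clustering_markers(events)
    mat <- marker_matrix(events, markers)
  } else {
    mat <- as.matrix(events)
  }
  keep <- !is.na(assignments)
  mat <- mat[keep, , drop = FALSE]
  cl <- factor(assignments[keep])
  if (nlevels(cl) < 2) abort("At least two clusters are required for scaling.")
  mfi <- rowsum(mat, cl) / as.vector(table(cl))
  rownames(mfi) <- levels(cl)

  rng_min <- apply(mfi, 2, min)
  rng_max <- apply(mfi, 2, max)
  span <- rng_max - rng_min
  scaled <- sweep(mfi, 2, rng_min)
  scaled <- sweep(scaled, 2, ifelse(span > 0, span, 1), "/")
  scaled[, span == 0] <- 0                  # tie convention: constant -> 0
  present <- scaled >= threshold

  row_order <- if (nrow(scaled) > 2) {
    hclust(dist(scaled), method = "average")$order
  } else seq_len(nrow(scaled))
  col_order <- if (ncol(scaled) > 2) {
    hclust(dist(t(scaled)), method = "average")$order
  } else seq_len(ncol(scaled))

  structure(
    list(mfi = mfi, scaled = scaled, present = present,
         row_order = row_order, col_order = col_order,
         threshold = threshold),
    class = "cluster_profile"
  )
}

#' @rdname profile_clusters
#' @param x A `cluster_profile`.
#' @param ... Unused.
#' @export
tidy.cluster_profile <- function(x, ...) {
  out <- as_tibble(x$mfi, rownames = "cluster") |>
    tidyr::pivot_longer(-"cluster", names_to = "marker", values_to = "mfi")
  out$scaled <- as.vector(t(x$scaled))
  out$present <- as.vector(t(x$present))
  out
}

#' Delta mean cluster abundance between product groups
#'
#' Per-cluster difference of group mean abundances. The fixed sign
#' convention is C7R-minus-GD2-only (`group_a` minus `group_b`), echoed in
#' the `convention` attribute of the result. Because abundances sum to 100
#' within each sample, deltas sum to 0 across clusters.
#'
#' @param tab A [cluster_abundance()] table with a grouping column.
#' @param group_a,group_b Group labels (delta = mean A - mean B).
#' @param group_col Name of the grouping column.
#' @return Tibble `cluster`, `mean_a`, `mean_b`, `delta` with a
#'   `convention` attribute.
#' @export
delta_mean_abundance <- function(tab, group_a = "C7R", group_b = "GD2",
                                 group_col = "product_group") {
  g <- tab[[group_col]]
  a <- tab[g == group_a, , drop = FALSE]
  b <- tab[g == group_b, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) {
    abort("Both groups must be non-empty.")
  }
  cl <- abundance_cluster_cols(tab)
  mean_a <- colMeans(a[, cl, drop = FALSE], na.rm = TRUE)
  mean_b <- colMeans(b[, cl, drop = FALSE], na.rm = TRUE)
  out <- tibble(
    cluster = sub("^cl_", "", cl),
    mean_a = unname(mean_a), mean_b = unname(mean_b),
    delta = unname(mean_a - mean_b)
  )
  attr(out, "convention") <- paste0("delta = mean(", group_a, ") - mean(",
                                    group_b, ")")
  out
}

#' Rank association between cluster abundance and clinical outcome
#'
#' Spearman correlation of each cluster's per-sample abundance with the
#' ordinal outcome (PD = 0 < SD = 1 < PR = 2), formalising the "lowest in
#' PD, highest in PR" trend as a monotone association. Constant abundances
#' give an undefined correlation, returned as `NA` and flagged.
#'
#' @param tab A [cluster_abundance()] table with an `outcome` column.
#' @param outcome_col Column holding `"PD"`/`"SD"`/`"PR"` labels (or a
#'   numeric rank).
#' @return Tibble `cluster`, `rho`, `defined`.
#' @export
outcome_association <- function(tab, outcome_col = "outcome") {
  y <- tab[[outcome_col]]
  if (is.character(y) || is.factor(y)) y <- outcome_rank(as.character(y))
  ok <- !is.na(y)
  if (sum(ok) < 3) abort("At least 3 samples with outcomes are required.")
  cl <- abundance_cluster_cols(tab)
  rho <- vapply(cl, function(cc) {
    x <- tab[[cc]][ok]
    if (sd(x, na.rm = TRUE) == 0 || sd(y[ok]) == 0) return(NA_real_)
    suppressWarnings(cor(x, y[ok], method = "spearman",
                         use = "complete.obs"))
  }, numeric(1))
  tibble(cluster = sub("^cl_", "", cl), rho = unname(rho),
         defined = !is.na(rho))
}
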