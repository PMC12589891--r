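#' Build a hierarchical gate tree
#'
#' A gate tree is a tibble of nodes, each restricting one channel to an
#' interval under a named parent; a node with several rows is a conjunction
#' (e.g. a 2-D rectangle uses two rows). The implicit root `"all"` contains
#' every event, and each node selects the subset of its parent satisfying
#' its predicates, so child populations are always subsets of their parents.
#' Thresholds are interpreted on the event table's current scale
#' (`scale_state`); record gates on the scale you gate on.
#'
#' @param ... `gate_node()` entries.
#' @return Tibble with columns `node`, `parent`, `channel`, `lower`,
#'   `upper`.
#' @export
#' @examples
#' tree <- gate_tree(
#'   gate_node("viable", "all", "Viability", upper = 100),
#'   gate_node("T cells", "viable", "CD3", lower = 500)
#' )
gate_tree <- function(...) {
  tree <- dplyr::bind_rows(...)
  known <- c("all", tree$node)
  orphan <- setdiff(tree$parent, known)
  if (length(orphan)) {
    abort(paste0("Gate parents not defined: ", paste(orphan, collapse = ", ")))
  }
  tree
}

#' @rdname gate_tree
#' @param node,parent Node label and parent label (`"all"` for the root).
#' @param channel Channel the predicate applies to.
#' @param lower,upper Interval bounds (events kept satisfy
#'   `lower <= x <= upper`); omit one side for a 1-D threshold.
#' @export
gate_node <- function(node, parent, channel, lower = -Inf, upper = Inf) {
  tibble(node = node, parent = parent, channel = channel,
         lower = lower, upper = upper)
}

gate_path <- function(tree, node) {
  path <- character()
  cur <- node
  while (cur != "all") {
    if (!cur %in% tree$node) abort(paste0("Unknown gate node: ", cur))
    path <- c(cur, path)
    cur <- tree$parent[match(cur, tree$node)][1]
  }
  path
}

#' Apply a gate tree down to a node
#'
#' Returns the events satisfying every predicate on the path from the root
#' to `node`. An empty result is a valid (empty) event table, not an error;
#' metadata columns and attributes are preserved.
#'
#' @param events An event table.
#' @param tree A [gate_tree()].
#' @param node Target node label (`"all"` returns the input).
#' @return Gated event table.
#' @export
apply_gates <- function(events, tree, node = "all") {
  keep <- rep(TRUE, nrow(events))
  for (nd in gate_path(tree, node)) {
    preds <- tree[tree$node == nd, , drop = FALSE]
    for (i in seq_len(nrow(preds))) {
      ch <- preds$channel[i]
      if (!ch %in% names(events)) abort(paste0("Channel not present: ", ch))
      x <- events[[ch]]
      keep <- keep & x >= preds$lower[i] & x <= preds$upper[i]
    }
  }
  out <- events[keep, , drop = FALSE]
  set_event_attrs(out, markers = event_markers(events),
                  state = scale_state(events))
}

#' Define a boolean marker signature
#'
#' A conjunction of per-marker positivity/negativity terms evaluated inside
#' a parent population (typically single, viable CD3+ CD8+ cells). The four
#' default signatures mirror the response-associated CD8 phenotypes:
#' cytotoxicity (GrzB+ CD26+), activation (BCL-2+ CD26+ CD154+),
#' infiltration (CD103+ TIGIT+ CD26+) and resilience (TIGIT+).
#'
#' @param name Signature label.
#' @param markers Markers in the conjunction (may be empty: the vacuous
#'   conjunction matches every parent event).
#' @param polarity `"+"` or `"-"` per marker, recycled.
#' @return A `boolean_signature` list.
#' @export
boolean_signature <- function(name, markers, polarity = "+") {
  polarity <- rep_len(polarity, length(markers))
  stopifnot(all(polarity %in% c("+", "-")))
  structure(list(name = name, markers = markers, polarity = polarity),
            class = "boolean_signature")
}

#' @rdname boolean_signature
#' @export
default_signatures <- function() {
  list(
    cytotoxicity = boolean_signature("cytotoxicity", c("GrzB", "CD26")),
    activation = boolean_signature("activation", c("BCL-2", "CD26", "CD154")),
    infiltration = boolean_signature("infiltration", c("CD103", "TIGIT", "CD26")),
    resilience = boolean_signature("resilience", "TIGIT")
  )
}

#' Frequency of a boolean signature in a parent population
#'
#' Percentage of parent events positive (or negative) for every marker in
#' the signature, with positivity defined by per-marker thresholds (set from
#' FMO-style controls or configuration, on the table's current scale).
#'
#' @param events Parent-population event table (already gated).
#' @param sig A [boolean_signature()].
#' @param thresholds Named numeric vector of positivity thresholds covering
#'   the signature's markers.
#' @return Percentage in \[0, 100\]; `NA` with a warning when the parent is
#'   empty.
#' @export
signature_frequency <- function(events, sig, thresholds) {
  if (nrow(events) == 0) {
    warn(paste0("Empty parent population for signature '", sig$name,
                "'; frequency undefined."))
    return(NA_real_)
  }
  missing_th <- setdiff(sig$markers, names(thresholds))
  if (length(missing_th)) {
    abort(paste0("No threshold for marker(s): ",
                 paste(missing_th, collapse = ", ")))
  }
  keep <- rep(TRUE, nrow(events))
  for (i in seq_along(sig$markers)) {
    m <- sig$markers[i]
    if (!m %in% names(events)) abort(paste0("Marker not in panel: ", m))
    pos <- events[[m]] >= thresholds[[m]]
    keep <- keep & if (sig$polarity[i] == "+") pos else !pos
  }
  100 * sum(keep) / nrow(events)
}

#' Read a gate tree and signatures from YAML
#'
#' Configuration format: a `gates` list of `{node, parent, channel, lower,
#' upper}` entries and a `signatures` list of `{name, markers, polarity}`.
#'
#' @param path YAML file.
#' @return List with `$tree` and `$signatures`.
#' @export
read_gating_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  tree <- dplyr::bind_rows(lapply(cfg$gates, function(g) {
    gate_node(g$node, g$parent, g$channel,
              lower = g$lower %||% -Inf, upper = g$upper %||% Inf)
  }))
  sigs <- lapply(cfg$signatures, function(s) {
    boolean_signature(s$name, unlist(s$markers),
                      unlist(s$polarity %||% "+"))
  })
  names(sigs) <- vapply(sigs, `[[`, character(1), "name")
  list(tree = gate_tree(tree), signatures = sigs)
}
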