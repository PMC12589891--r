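#' The 33-marker spectral flow panel
#'
#' Marker names of the full-spectrum flow cytometry panel used throughout the
#' package: lineage (CD3, CD4, CD8), memory differentiation (CD45RA, CCR7,
#' CD95), activation (CD25, CD69-like CD137, HLA-DR, CD154), cytokines (IFN-g,
#' TNF-a, IL-2, IL-4, IL-17A, IL-22), cytotoxicity (GrzB), apoptosis
#' regulation (BCL-2), proliferation (Ki67), tissue infiltration (CD103,
#' CD26, CXCR3, CCR4, CCR6), checkpoints (PD-1, TIM-3, LAG-3, CTLA-4, TIGIT,
#' BTLA), transgene detection (CAR via the 14g2a idiotype, C7R via CD34), and
#' a viability dye.
#'
#' @return Character vector of 33 channel names.
#' @export
#' @examples
#' default_panel()
default_panel <- function() {
  c(
    "CD3", "CD4", "CD8", "CD45RA", "CCR7", "CD95", "CD25", "CD137",
    "HLA-DR", "CD154", "IFN-g", "TNF-a", "IL-2", "IL-4", "IL-17A", "IL-22",
    "GrzB", "BCL-2", "Ki67", "CD103", "CD26", "CXCR3", "CCR4", "CCR6",
    "PD-1", "TIM-3", "LAG-3", "CTLA-4", "TIGIT", "BTLA",
    "CAR-14g2a", "C7R-CD34", "Viability"
  )
}

# Channels excluded from clustering/embedding: pre-filtering and transgene
# detection channels (viability, CD3, CAR, C7R).
clustering_exclusions <- function() {
  c("CD3", "Viability", "CAR-14g2a", "C7R-CD34")
}

#' Markers used for clustering
#'
#' The study design clusters on all panel markers except the viability dye,
#' CD3 (both used for pre-filtering) and the transgene-detection channels
#' (CAR idiotype, C7R/CD34).
#'
#' @param events An event table.
#' @return Character vector of marker names.
#' @export
clustering_markers <- function(events) {
  setdiff(event_markers(events), clustering_exclusions())
}
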