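#' Default human gene panels
#'
#' Standard marker lists used throughout the pipeline:
#' \itemize{
#'   \item T cell surface markers: CD8A, CD8B, CD4, CD3D, CD3E, CD3G.
#'   \item Exhaustion markers: PDCD1, LAG3, HAVCR2, TIGIT, CTLA4, ENTPD1, TOX.
#'   \item Chemokine trend sets: CXCL9/10/11 combined, CCL4/5 combined,
#'     CXCL16 alone.
#'   \item Macrophage markers: CD68, CD163, CD80, CD14.
#'   \item TCR variable-gene pattern: TRAV/TRAJ/TRBV prefixes; BCR pattern:
#'     IGHV/IGKV/IGLV prefixes.
#' }
#' Stage-gene candidates are a broad panel of T-cell differentiation-state
#' markers (naive/memory, effector, residency, proliferation); only the
#' candidates positively correlated with T-marker load in the data at hand
#' are used (\code{\link{selectStageGenes}}).
#'
#' @return A \linkS4class{GenePanels} object.
#' @examples
#' defaultGenePanels()
#' @export
defaultGenePanels <- function() {
  new("GenePanels",
      tMarkers = c("CD8A", "CD8B", "CD4", "CD3D", "CD3E", "CD3G"),
      exhaustionMarkers = c("PDCD1", "LAG3", "HAVCR2", "TIGIT", "CTLA4",
                            "ENTPD1", "TOX"),
      stageGeneCandidates = c("CCR7", "SELL", "TCF7", "IL7R", "CD27", "CD28",
                              "GZMA", "GZMB", "GZMK", "PRF1", "IFNG", "TNF",
                              "CD69", "ITGAE", "CX3CR1", "KLRG1", "EOMES",
                              "MKI67"),
      chemokineSets = list(cxcl9_10_11 = c("CXCL9", "CXCL10", "CXCL11"),
                           ccl4_5 = c("CCL4", "CCL5"),
                           cxcl16 = "CXCL16"),
      macrophageMarkers = c("CD68", "CD163", "CD80", "CD14"),
      vgenePatterns = list(tcr = "^TRAV|^TRAJ|^TRBV",
                           bcr = "^IGHV|^IGKV|^IGLV"))
}
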