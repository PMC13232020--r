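#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assayNames colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' STDataset: a spatial transcriptomics slide
#'
#' Container for a spot (or pixel) by gene count matrix plus spatial
#' coordinates and platform metadata. Extends
#' \linkS4class{SummarizedExperiment}: genes are rows, spots are columns.
#' The \code{"counts"} assay holds raw UMI counts; \code{\link{normalizeCounts}}
#' adds a \code{"tpm"} assay. Per-spot micron coordinates live in
#' \code{colData} columns \code{x_um} / \code{y_um}; \code{umi_total} caches
#' the per-spot column sum. Platform (\code{"visium"} or \code{"visium_hd"})
#' and center-to-center pitch in microns are kept in \code{metadata()}.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}
#' @aliases STDataset-class
#' @exportClass STDataset
setClass("STDataset", contains = "SummarizedExperiment")

setValidity("STDataset", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  cd <- colData(object)
  need <- c("x_um", "y_um", "umi_total")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("colData must contain", paste(need, collapse = ", ")))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "spot identifiers must be unique")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene names must be unique")
  if (all(need %in% colnames(cd))) {
    if (!all(is.finite(cd$x_um)) || !all(is.finite(cd$y_um)))
      msg <- c(msg, "spot coordinates must be finite")
    cnt <- assay(object, "counts")
    if (min(cnt) < 0) msg <- c(msg, "counts must be non-negative")
    if (!isTRUE(all.equal(unname(Matrix::colSums(cnt)),
                          unname(as.numeric(cd$umi_total)))))
      msg <- c(msg, "umi_total must equal per-spot count sums")
  }
  pl <- metadata(object)$platform
  if (is.null(pl) || !pl %in% c("visium", "visium_hd"))
    msg <- c(msg, "metadata()$platform must be 'visium' or 'visium_hd'")
  if (is.null(metadata(object)$pitch_um) || metadata(object)$pitch_um <= 0)
    msg <- c(msg, "metadata()$pitch_um must be a positive number")
  if (length(msg)) msg else TRUE
})

#' Construct an STDataset
#'
#' @param counts gene x spot matrix (dense or \pkg{Matrix} sparse) of
#'   non-negative integer UMI counts, with unique dimnames.
#' @param xy two-column matrix or data.frame of spot coordinates in microns,
#'   one row per spot (same order as \code{colnames(counts)}).
#' @param platform \code{"visium"} or \code{"visium_hd"}.
#' @param pitch_um center-to-center spot spacing in microns.
#' @return An \linkS4class{STDataset}.
#' @examples
#' cnt <- matrix(rpois(30, 5), nrow = 5,
#'               dimnames = list(paste0("G", 1:5), paste0("S", 1:6)))
#' ds <- STDataset(cnt, cbind(x = 1:6 * 110, y = 0))
#' umiTotals(ds)
#' @export
STDataset <- function(counts, xy, platform = c("visium", "visium_hd"),
                      pitch_um = 110) {
  platform <- match.arg(platform)
  stopifnot(nrow(xy) == ncol(counts))
  cd <- DataFrame(x_um = as.numeric(xy[, 1]), y_um = as.numeric(xy[, 2]),
                  umi_total = as.numeric(Matrix::colSums(counts)),
                  row.names = colnames(counts))
  se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
  metadata(se)$platform <- platform
  metadata(se)$pitch_um <- pitch_um
  new("STDataset", se)
}

#' @describeIn STDataset spot coordinates in microns (matrix with columns x, y)
#' @param ds,object an \code{STDataset}
#' @export
spotCoords <- function(ds) {
  cbind(x = colData(ds)$x_um, y = colData(ds)$y_um)
}

#' @describeIn STDataset per-spot total UMI counts
#' @export
umiTotals <- function(ds) {
  stats::setNames(colData(ds)$umi_total, colnames(ds))
}

#' @describeIn STDataset platform string
#' @export
stPlatform <- function(ds) metadata(ds)$platform

#' @describeIn STDataset spot pitch in microns
#' @export
pitchUm <- function(ds) metadata(ds)$pitch_um

#' @describeIn STDataset TPM-like normalized matrix (requires
#'   \code{\link{normalizeCounts}} first)
#' @export
tpmMatrix <- function(ds) {
  if (!"tpm" %in% assayNames(ds))
    stop("no 'tpm' assay: run normalizeCounts() first")
  assay(ds, "tpm")
}

setMethod("show", "STDataset", function(object) {
  cat("STDataset (", metadata(object)$platform, ", pitch ",
      metadata(object)$pitch_um, " um): ",
      nrow(object), " genes x ", ncol(object), " spots\n", sep = "")
  callNextMethod()
})

#' GenePanels: marker gene configuration
#'
#' Named gene lists driving T-spot detection, exhaustion scoring, stage-gene
#' selection, chemokine/macrophage trend tests and TCR/BCR variable-gene
#' matching. \code{\link{defaultGenePanels}} returns the standard human panels.
#'
#' @slot tMarkers T cell surface markers.
#' @slot exhaustionMarkers T cell exhaustion markers.
#' @slot stageGeneCandidates candidate T-cell stage genes for trail selection.
#' @slot chemokineSets named list of chemokine gene sets for trend testing.
#' @slot macrophageMarkers macrophage markers for trend testing.
#' @slot vgenePatterns named list of regex patterns (\code{tcr}, \code{bcr})
#'   matching variable-gene symbols.
#' @exportClass GenePanels
setClass("GenePanels", representation(
  tMarkers = "character",
  exhaustionMarkers = "character",
  stageGeneCandidates = "character",
  chemokineSets = "list",
  macrophageMarkers = "character",
  vgenePatterns = "list"
))

setValidity("GenePanels", function(object) {
  msg <- character()
  for (s in c("tMarkers", "exhaustionMarkers", "stageGeneCandidates",
              "macrophageMarkers"))
    if (length(slot(object, s)) == 0) msg <- c(msg, paste(s, "is empty"))
  if (length(object@chemokineSets) == 0 ||
      is.null(names(object@chemokineSets)))
    msg <- c(msg, "chemokineSets must be a non-empty named list")
  if (!all(c("tcr", "bcr") %in% names(object@vgenePatterns)))
    msg <- c(msg, "vgenePatterns must name 'tcr' and 'bcr' patterns")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GenePanels", function(object) {
  cat("GenePanels:",
      length(object@tMarkers), "T markers,",
      length(object@exhaustionMarkers), "exhaustion markers,",
      length(object@stageGeneCandidates), "stage candidates,",
      length(object@chemokineSets), "chemokine sets\n")
})

#' GeneSetList: named gene sets (GMT collections)
#'
#' @slot sets named list of character vectors of gene symbols.
#' @slot universe optional background gene list (character(0) if unset).
#' @seealso \code{\link{readGmt}}, \code{\link{oraFisher}}
#' @exportClass GeneSetList
setClass("GeneSetList", representation(sets = "list", universe = "character"))

setValidity("GeneSetList", function(object) {
  msg <- character()
  if (length(object@sets)) {
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
      msg <- c(msg, "set names must be present and unique")
    if (any(lengths(object@sets) == 0)) msg <- c(msg, "sets must be non-empty")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneSetList construct from a named list
#' @param sets named list of gene symbol vectors
#' @param universe optional background gene list
#' @export
GeneSetList <- function(sets, universe = character(0)) {
  sets <- lapply(sets, function(g) unique(as.character(g)))
  new("GeneSetList", sets = sets, universe = as.character(universe))
}

#' @describeIn GeneSetList the named list of sets
#' @param x a GeneSetList
#' @export
geneSets <- function(x) x@sets

setMethod("show", "GeneSetList", function(object) {
  cat("GeneSetList with", length(object@sets), "sets")
  if (length(object@universe))
    cat(" (universe:", length(object@universe), "genes)")
  cat("\n")
})

setMethod("length", "GeneSetList", function(x) length(x@sets))

#' NodeTable: trail-search units with exhaustion scores
#'
#' One row per node. For standard Visium each node is a single T-cell spot;
#' for Visium HD a node is a group of adjacent pixels with similar exhaustion
#' scores (\code{\link{hdAggregate}}). Column \code{z} is the exhaustion
#' score, shifted so its minimum is 0; \code{x}/\code{y} are centroid
#' coordinates in microns.
#'
#' @slot nodes data.frame with columns \code{node_id}, \code{x}, \code{y},
#'   \code{z}, \code{t_marker_sum}, \code{umi_total}.
#' @slot members named list mapping node_id to member spot/pixel ids.
#' @exportClass NodeTable
setClass("NodeTable", representation(nodes = "data.frame", members = "list"))

setValidity("NodeTable", function(object) {
  msg <- character()
  need <- c("node_id", "x", "y", "z", "t_marker_sum", "umi_total")
  if (!all(need %in% colnames(object@nodes)))
    msg <- c(msg, paste("nodes needs columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@nodes$node_id))
      msg <- c(msg, "node_id must be unique")
    if (!all(is.finite(object@nodes$z))) msg <- c(msg, "z must be finite")
    if (nrow(object@nodes) && abs(min(object@nodes$z)) > 1e-8)
      msg <- c(msg, "z must be shifted so min(z) == 0")
    mem <- unlist(object@members, use.names = FALSE)
    if (anyDuplicated(mem))
      msg <- c(msg, "every spot must belong to exactly one node")
    if (!setequal(names(object@members), object@nodes$node_id))
      msg <- c(msg, "members must be named by node_id")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn NodeTable construct from a node data.frame
#' @param nodes data.frame (see slots)
#' @param members named list of member spot ids; defaults to singleton
#'   membership (node_id itself)
#' @export
NodeTable <- function(nodes, members = NULL) {
  nodes$node_id <- as.character(nodes$node_id)
  if (is.null(members))
    members <- stats::setNames(as.list(nodes$node_id), nodes$node_id)
  rownames(nodes) <- nodes$node_id
  new("NodeTable", nodes = nodes, members = members)
}

#' @describeIn NodeTable the node data.frame
#' @param x a NodeTable
#' @export
nodeData <- function(x) x@nodes

#' @describeIn NodeTable named list of member spot ids per node
#' @export
nodeMembers <- function(x) x@members

#' @describeIn NodeTable node identifiers
#' @export
nodeIds <- function(x) x@nodes$node_id

#' @describeIn NodeTable exhaustion scores named by node
#' @export
exhaustionZ <- function(x) stats::setNames(x@nodes$z, x@nodes$node_id)

setMethod("show", "NodeTable", function(object) {
  cat("NodeTable:", nrow(object@nodes), "nodes; z range [",
      if (nrow(object@nodes)) signif(min(object@nodes$z), 4) else NA, ",",
      if (nrow(object@nodes)) signif(max(object@nodes$z), 4) else NA, "]\n")
})

setMethod("length", "NodeTable", function(x) nrow(x@nodes))

#' TrailGraph: directed exhaustion-ascent graph over T-cell nodes
#'
#' Edges connect spatial neighbors (2D distance below \code{dMax}) and point
#' from the lower- to the higher-exhaustion node; the edge weight is the
#' difference in exhaustion score. Score ties are oriented from the smaller
#' to the larger node_id, which keeps the graph acyclic.
#'
#' @slot nodes the \linkS4class{NodeTable} the graph was built on.
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{weight}.
#' @slot dMax adjacency threshold in microns.
#' @exportClass TrailGraph
setClass("TrailGraph", representation(nodes = "NodeTable",
                                      edges = "data.frame",
                                      dMax = "numeric"))

setValidity("TrailGraph", function(object) {
  msg <- character()
  if (!all(c("from", "to", "weight") %in% colnames(object@edges)))
    msg <- c(msg, "edges needs columns from, to, weight")
  else if (nrow(object@edges)) {
    if (any(object@edges$weight < 0)) msg <- c(msg, "weights must be >= 0")
    if (any(object@edges$from == object@edges$to))
      msg <- c(msg, "self-edges are not allowed")
  }
  if (object@dMax <= 0) msg <- c(msg, "dMax must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn TrailGraph edge data.frame (from, to, weight)
#' @param g a TrailGraph
#' @export
trailEdges <- function(g) g@edges

#' @describeIn TrailGraph the underlying NodeTable
#' @export
graphNodes <- function(g) g@nodes

setMethod("show", "TrailGraph", function(object) {
  cat("TrailGraph:", length(object@nodes), "nodes,",
      nrow(object@edges), "directed edges (dMax =", object@dMax, "um)\n")
})

#' Trail: an ordered sequence of adjacent T-cell nodes
#'
#' @slot nodeSeq ordered node ids; position i has 1-based index i.
#' @slot method character vector of discovery methods
#'   (\code{"dijkstra"}, \code{"line3d"}, or both after deduplication).
#' @slot spanUm 2D distance in microns between first and last node.
#' @slot zProfile exhaustion scores along the trail.
#' @exportClass Trail
setClass("Trail", representation(nodeSeq = "character", method = "character",
                                 spanUm = "numeric", zProfile = "numeric"))

setValidity("Trail", function(object) {
  msg <- character()
  if (length(object@nodeSeq) < 2) msg <- c(msg, "a trail needs >= 2 nodes")
  if (anyDuplicated(object@nodeSeq)) msg <- c(msg, "nodes must not repeat")
  if (length(object@zProfile) != length(object@nodeSeq))
    msg <- c(msg, "zProfile length must match nodeSeq")
  if (!all(object@method %in% c("dijkstra", "line3d", "control",
                                "alternative", "planted")))
    msg <- c(msg, "unknown method tag")
  if (length(msg)) msg else TRUE
})

#' @describeIn Trail construct a Trail from a node sequence
#' @param nodeSeq ordered node ids
#' @param nodes the NodeTable the ids refer to
#' @param method discovery method tag(s)
#' @export
Trail <- function(nodeSeq, nodes, method) {
  nd <- nodeData(nodes)
  i <- match(nodeSeq, nd$node_id)
  if (anyNA(i)) stop("trail references unknown node ids")
  n <- length(nodeSeq)
  new("Trail", nodeSeq = as.character(nodeSeq), method = method,
      spanUm = sqrt((nd$x[i[n]] - nd$x[i[1]])^2 + (nd$y[i[n]] - nd$y[i[1]])^2),
      zProfile = nd$z[i])
}

#' @describeIn Trail ordered node ids
#' @param trail,x a Trail
#' @export
trailNodes <- function(trail) trail@nodeSeq

#' @describeIn Trail 1-based spot indices along the trail
#' @export
trailIndex <- function(trail) seq_along(trail@nodeSeq)

#' @describeIn Trail 2D start-to-end span in microns
#' @export
trailSpan <- function(trail) trail@spanUm

#' @describeIn Trail exhaustion-score profile
#' @export
trailZ <- function(trail) trail@zProfile

#' @describeIn Trail discovery method tag(s)
#' @export
trailMethod <- function(trail) trail@method

setMethod("show", "Trail", function(object) {
  cat("Trail [", paste(object@method, collapse = "+"), "]: ",
      length(object@nodeSeq), " nodes, span ", round(object@spanUm),
      " um, z ", signif(object@zProfile[1], 3), " -> ",
      signif(object@zProfile[length(object@zProfile)], 3), "\n", sep = "")
})

setMethod("length", "Trail", function(x) length(x@nodeSeq))

#' Validate a trail against the graph constraints
#'
#' Single validator used both in tests and at runtime: checks consecutive
#' adjacency (2D distance below \code{dMax}), no repeated nodes, minimum
#' length and minimum start-to-end span.
#'
#' @param trail a \linkS4class{Trail} or character vector of node ids
#' @param nodes the \linkS4class{NodeTable}
#' @param dMax adjacency threshold in microns
#' @param minNodes minimum number of nodes
#' @param minSpan minimum 2D span in microns
#' @return TRUE, or a character string describing the first violated
#'   constraint.
#' @export
validateTrail <- function(trail, nodes, dMax = 130, minNodes = 6,
                          minSpan = 500) {
  seqIds <- if (is(trail, "Trail")) trailNodes(trail) else as.character(trail)
  nd <- nodeData(nodes)
  i <- match(seqIds, nd$node_id)
  if (anyNA(i)) return("unknown node id")
  if (anyDuplicated(seqIds)) return("repeated node")
  if (length(i) < minNodes) return(sprintf("fewer than %d nodes", minNodes))
  d <- sqrt(diff(nd$x[i])^2 + diff(nd$y[i])^2)
  if (any(d >= dMax)) return("consecutive nodes not adjacent")
  n <- length(i)
  span <- sqrt((nd$x[i[n]] - nd$x[i[1]])^2 + (nd$y[i[n]] - nd$y[i[1]])^2)
  if (span < minSpan) return(sprintf("span below %g um", minSpan))
  TRUE
}
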