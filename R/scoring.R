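#' Identify T-cell-infiltrated spots
#'
#' A spot is T-cell infiltrated when its summed raw counts over the available
#' T cell surface markers (CD8A, CD8B, CD4, CD3D, CD3E, CD3G by default)
#' exceed \code{threshold}. The default threshold of 0 calls any spot with at
#' least one detected T-marker transcript.
#'
#' @param ds an \linkS4class{STDataset}.
#' @param panels a \linkS4class{GenePanels} (default panels if missing).
#' @param threshold minimum summed raw T-marker count, exclusive (default 0).
#' @return Character vector of T-spot ids, in dataset order.
#' @export
detectTSpots <- function(ds, panels = defaultGenePanels(), threshold = 0) {
  mk <- intersect(panels@tMarkers, rownames(ds))
  if (length(mk) == 0)
    stop("none of the T cell markers (", paste(panels@tMarkers, collapse = ", "),
         ") are present in the dataset")
  s <- Matrix::colSums(assay(ds, "counts")[mk, , drop = FALSE])
  colnames(ds)[s > threshold]
}

#' Exhaustion score per T spot
#'
#' Regresses the per-spot sum of exhaustion-marker expression (PDCD1, LAG3,
#' HAVCR2, TIGIT, CTLA4, ENTPD1, TOX) on the per-spot sum of T-cell-marker
#' expression across T spots, by ordinary least squares. The score z is the
#' regression residual, shifted so the smallest score is 0: it captures how
#' exhausted the T cells in a spot are after controlling for how many T cells
#' it contains. By default both sums are computed on TPM-normalized
#' expression so that sequencing depth is also controlled; set
#' \code{use = "counts"} for raw counts.
#'
#' @param ds an \linkS4class{STDataset} (normalized when \code{use = "tpm"}).
#' @param tSpots spot ids from \code{\link{detectTSpots}}.
#' @param panels a \linkS4class{GenePanels}.
#' @param use assay to sum over: \code{"tpm"} (default) or \code{"counts"}.
#' @return A \linkS4class{NodeTable} with one node per T spot; the fitted
#'   slope, intercept and R-squared are attached as attribute \code{"fit"}
#'   of the returned object's node data.frame.
#' @export
exhaustionScore <- function(ds, tSpots, panels = defaultGenePanels(),
                            use = c("tpm", "counts")) {
  use <- match.arg(use)
  if (length(tSpots) < 3) stop("need at least 3 T spots")
  mat <- if (use == "tpm") tpmMatrix(ds) else as.matrix(assay(ds, "counts"))
  mat <- mat[, tSpots, drop = FALSE]
  tm <- intersect(panels@tMarkers, rownames(mat))
  em <- intersect(panels@exhaustionMarkers, rownames(mat))
  if (length(tm) == 0) stop("no T cell markers in the dataset")
  if (length(em) == 0) stop("no exhaustion markers in the dataset")
  tSum <- colSums(mat[tm, , drop = FALSE])
  eSum <- colSums(mat[em, , drop = FALSE])
  if (stats::var(tSum) == 0)
    stop("T-marker sums are constant across T spots; ",
         "review the T-spot threshold")
  fit <- stats::lm(eSum ~ tSum)
  z <- stats::residuals(fit)
  z <- z - min(z)
  xy <- spotCoords(ds)[match(tSpots, colnames(ds)), , drop = FALSE]
  nodes <- data.frame(node_id = tSpots, x = xy[, 1], y = xy[, 2],
                      z = as.numeric(z), t_marker_sum = as.numeric(tSum),
                      umi_total = as.numeric(umiTotals(ds)[tSpots]),
                      stringsAsFactors = FALSE)
  attr(nodes, "fit") <- c(intercept = unname(stats::coef(fit)[1]),
                          slope = unname(stats::coef(fit)[2]),
                          r_squared = suppressWarnings(summary(fit)$r.squared))
  NodeTable(nodes)
}

#' Aggregate HD pixels into nodes by region growing
#'
#' Greedy region growing for Visium HD: pick an unassigned seed pixel,
#' collect the unassigned pixels within \code{radiusFactor * pitch} microns
#' whose exhaustion scores are within \code{tol} of the seed's, assign them
#' to one node, and repeat until every pixel is assigned. Seeds are visited
#' in descending T-marker load (ties by id) so the partition is
#' deterministic. Node score is the member mean; node coordinates the member
#' centroid; after aggregation scores are re-shifted so the minimum is 0.
#'
#' @param pixels a \linkS4class{NodeTable} of per-pixel scores, as returned
#'   by \code{\link{exhaustionScore}} on a Visium HD dataset.
#' @param pitch_um pixel pitch in microns.
#' @param radiusFactor search radius as a multiple of the pitch (default 5).
#' @param tol score similarity tolerance; default 5\% of the observed score
#'   range.
#' @return A \linkS4class{NodeTable} whose members partition the pixels.
#' @export
hdAggregate <- function(pixels, pitch_um, radiusFactor = 5, tol = NULL) {
  if (radiusFactor <= 0) stop("radiusFactor must be positive")
  nd <- nodeData(pixels)
  if (is.null(tol)) tol <- 0.05 * diff(range(nd$z))
  if (tol < 0) stop("tol must be non-negative")
  radius <- radiusFactor * pitch_um
  ord <- order(-nd$t_marker_sum, nd$node_id)
  assigned <- rep(FALSE, nrow(nd))
  out <- vector("list", nrow(nd))
  members <- list()
  k <- 0
  for (s in ord) {
    if (assigned[s]) next
    d2 <- (nd$x - nd$x[s])^2 + (nd$y - nd$y[s])^2
    grab <- !assigned & d2 <= radius^2 & abs(nd$z - nd$z[s]) <= tol
    assigned[grab] <- TRUE
    k <- k + 1
    id <- sprintf("node_%04d", k)
    out[[k]] <- data.frame(node_id = id,
                           x = mean(nd$x[grab]), y = mean(nd$y[grab]),
                           z = mean(nd$z[grab]),
                           t_marker_sum = sum(nd$t_marker_sum[grab]),
                           umi_total = sum(nd$umi_total[grab]),
                           stringsAsFactors = FALSE)
    members[[id]] <- nd$node_id[grab]
  }
  nodes <- do.call(rbind, out[seq_len(k)])
  nodes$z <- nodes$z - min(nodes$z)
  NodeTable(nodes, members)
}
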