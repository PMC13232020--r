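#' Per-node normalized expression
#'
#' Gene-by-node matrix of TPM-normalized expression; for aggregated (HD)
#' nodes the member-pixel mean is used.
#'
#' @param ds a normalized \linkS4class{STDataset}.
#' @param nodes a \linkS4class{NodeTable}.
#' @param genes gene subset (default all).
#' @return Numeric matrix, genes x nodes.
#' @export
nodeExpression <- function(ds, nodes, genes = rownames(ds)) {
  tpm <- tpmMatrix(ds)[intersect(genes, rownames(ds)), , drop = FALSE]
  mem <- nodeMembers(nodes)
  out <- vapply(nodeIds(nodes), function(id) {
    m <- mem[[id]]
    if (length(m) == 1) tpm[, m] else rowMeans(tpm[, m, drop = FALSE])
  }, numeric(nrow(tpm)))
  if (nrow(tpm) == 1)
    out <- matrix(out, nrow = 1, dimnames = list(rownames(tpm), nodeIds(nodes)))
  out
}

#' Select T-cell stage genes for trail selection
#'
#' From a list of candidate T-cell stage markers, keeps the genes whose
#' normalized expression across T spots is significantly positively
#' correlated with T-marker load (Pearson r > 0 with two-sided p < 0.05 by
#' default; Spearman available).
#'
#' @param mat gene x T-spot normalized matrix.
#' @param candidates candidate stage gene symbols.
#' @param tMarkerSum per-spot T-marker expression sum (same spot order).
#' @param alpha significance level (default 0.05).
#' @param method correlation type, \code{"pearson"} (default) or
#'   \code{"spearman"}.
#' @return Character vector of selected genes.
#' @export
selectStageGenes <- function(mat, candidates, tMarkerSum, alpha = 0.05,
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(candidates) == 0) stop("empty candidate list")
  if (ncol(mat) < 10) stop("need at least 10 T spots")
  candidates <- intersect(candidates, rownames(mat))
  keep <- vapply(candidates, function(g) {
    x <- as.numeric(mat[g, ])
    if (stats::sd(x) == 0 || stats::sd(tMarkerSum) == 0) return(FALSE)
    ct <- suppressWarnings(
      stats::cor.test(x, tMarkerSum, method = method, exact = FALSE))
    isTRUE(ct$estimate > 0 && ct$p.value < alpha)
  }, logical(1))
  candidates[keep]
}

#' Mean pairwise stage-gene correlation along a route
#'
#' Pearson correlation of the stage-gene expression vectors of every
#' unordered pair of nodes on the route, averaged. A pair involving a
#' zero-variance vector (e.g. an all-dropout spot) contributes 0.
#'
#' @param nodeSeq ordered node ids of the route.
#' @param stageExpr stage-gene x node normalized expression matrix
#'   (\code{\link{nodeExpression}} over >= 3 stage genes).
#' @return Mean pairwise correlation in [-1, 1].
#' @export
meanPairwiseCorrelation <- function(nodeSeq, stageExpr) {
  if (nrow(stageExpr) < 3) stop("need at least 3 stage genes")
  if (length(nodeSeq) < 2) stop("need at least 2 nodes")
  m <- stageExpr[, nodeSeq, drop = FALSE]
  sds <- apply(m, 2, stats::sd)
  cc <- suppressWarnings(stats::cor(m))
  cc[!is.finite(cc)] <- 0   # zero-variance vectors contribute 0
  if (any(sds == 0) && isTRUE(getOption("TcellTrails.verbose", FALSE)))
    message(sum(sds == 0), " zero-variance node vector(s) contribute 0")
  mean(cc[upper.tri(cc)])
}

# undirected adjacency over T nodes, from a TrailGraph
.undirectedAdjacency <- function(g) {
  nd <- nodeData(graphNodes(g))
  n <- nrow(nd)
  idx <- stats::setNames(seq_len(n), nd$node_id)
  e <- trailEdges(g)
  adj <- vector("list", n)
  if (nrow(e)) {
    fi <- unname(idx[e$from]); ti <- unname(idx[e$to])
    all <- data.frame(u = c(fi, ti), v = c(ti, fi))
    sp <- split(all$v, all$u)
    for (nm in names(sp)) adj[[as.integer(nm)]] <- sp[[nm]]
  }
  list(adj = adj, ids = nd$node_id, idx = idx)
}

#' Sample alternative routes for a trail
#'
#' Generates 5--15 alternative routes between the trail's start and end by
#' self-avoiding random walks on the undirected T-node adjacency graph: at
#' each step an unvisited neighbor is chosen uniformly, a dead end triggers
#' a restart, and walks that reach the end, are at least \code{minNodes}
#' long and differ from the trail itself are collected (no requirement on
#' the score direction). Deterministic given \code{seed}.
#'
#' @param g a \linkS4class{TrailGraph} (its undirected skeleton is used).
#' @param trail a \linkS4class{Trail} that passed \code{\link{filterTrails}}.
#' @param kMin,kMax route count bounds (defaults 5 and 15).
#' @param maxAttempts number of walks attempted (default 300).
#' @param maxLen walk length cap (default 4x the trail length).
#' @param minNodes minimum route length (default 6).
#' @param seed RNG seed for reproducibility.
#' @return List with \code{routes} (list of node-id vectors),
#'   \code{sufficient} (TRUE when at least \code{kMin} routes were found)
#'   and \code{trail}.
#' @export
sampleAlternativeRoutes <- function(g, trail, kMin = 5, kMax = 15,
                                    maxAttempts = 300, maxLen = NULL,
                                    minNodes = 6, seed = 1) {
  und <- .undirectedAdjacency(g)
  seqIds <- trailNodes(trail)
  s <- und$idx[[seqIds[1]]]
  e <- und$idx[[seqIds[length(seqIds)]]]
  if (is.null(maxLen)) maxLen <- 4 * length(seqIds)
  trailKey <- paste(seqIds, collapse = ">")
  routes <- list()
  seen <- character(0)
  withSeed(seed, {
    for (att in seq_len(maxAttempts)) {
      path <- s
      visited <- rep(FALSE, length(und$ids))
      visited[s] <- TRUE
      ok <- FALSE
      while (length(path) < maxLen) {
        u <- path[length(path)]
        if (u == e) { ok <- TRUE; break }
        nb <- und$adj[[u]]
        nb <- nb[!visited[nb]]
        if (length(nb) == 0) break
        v <- if (length(nb) == 1) nb else nb[sample.int(length(nb), 1)]
        visited[v] <- TRUE
        path <- c(path, v)
      }
      if (path[length(path)] == e) ok <- TRUE
      if (!ok || length(path) < minNodes) next
      key <- paste(und$ids[path], collapse = ">")
      if (key == trailKey || key %in% seen) next
      seen <- c(seen, key)
      routes[[length(routes) + 1L]] <- und$ids[path]
      if (length(routes) >= kMax) break
    }
  })
  list(routes = routes, sufficient = length(routes) >= kMin, trail = trail)
}

#' Finalize migration trails against their alternative routes
#'
#' A candidate trail is retained when its mean pairwise stage-gene
#' correlation is (a) larger than that of every one of its own alternative
#' routes and (b) larger than the \code{percentile}-th percentile of the
#' correlations of all alternative routes pooled across candidates.
#' Candidates with fewer than \code{kMin} alternatives are excluded and
#' reported (set \code{insufficientPolicy = "keep"} to retain them subject
#' to criterion (b) only).
#'
#' @param candidates list of \linkS4class{Trail}s.
#' @param altSets list of alternative-route sets from
#'   \code{\link{sampleAlternativeRoutes}}, parallel to \code{candidates}.
#' @param stageExpr stage-gene x node matrix (\code{\link{nodeExpression}}).
#' @param percentile pooled percentile threshold (default 85).
#' @param kMin minimum alternatives required (default 5).
#' @param insufficientPolicy \code{"drop"} (default) or \code{"keep"}.
#' @return List with \code{trails} (final list), \code{scores},
#'   \code{insufficient} (indices of candidates lacking alternatives) and
#'   \code{pooledCutoff}.
#' @export
finalizeTrails <- function(candidates, altSets, stageExpr, percentile = 85,
                           kMin = 5,
                           insufficientPolicy = c("drop", "keep")) {
  insufficientPolicy <- match.arg(insufficientPolicy)
  stopifnot(length(candidates) == length(altSets))
  scoreOf <- function(seqIds) meanPairwiseCorrelation(seqIds, stageExpr)
  candScore <- vapply(candidates, function(tr) scoreOf(trailNodes(tr)),
                      numeric(1))
  altScores <- lapply(altSets, function(as)
    vapply(as$routes, scoreOf, numeric(1)))
  pooled <- unlist(altScores)
  cutoff <- if (length(pooled)) {
    stats::quantile(pooled, percentile / 100, names = FALSE)
  } else -Inf
  nAlt <- lengths(altScores)
  insufficient <- which(nAlt < kMin)
  keep <- logical(length(candidates))
  for (i in seq_along(candidates)) {
    if (nAlt[i] < kMin) {
      keep[i] <- insufficientPolicy == "keep" && candScore[i] > cutoff
    } else {
      keep[i] <- candScore[i] > max(altScores[[i]]) && candScore[i] > cutoff
    }
  }
  list(trails = candidates[keep], scores = candScore,
       keep = keep, insufficient = insufficient, pooledCutoff = cutoff)
}
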