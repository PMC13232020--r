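#' Build the directed exhaustion-ascent graph
#'
#' Connects every pair of nodes closer than \code{dMax} in 2D with a single
#' directed edge pointing from the lower- to the higher-exhaustion node,
#' weighted by the difference in exhaustion score. Equal scores are oriented
#' from the smaller to the larger node_id (weight 0), which keeps the graph
#' acyclic.
#'
#' @param nodes a \linkS4class{NodeTable}.
#' @param dMax adjacency threshold in microns (default 130; on the standard
#'   Visium lattice adjacent spots sit ~110 um apart, so this captures
#'   exactly the 6 hexagonal neighbors).
#' @return A \linkS4class{TrailGraph}.
#' @export
buildTrailGraph <- function(nodes, dMax = 130) {
  if (dMax <= 0) stop("dMax must be positive")
  nd <- nodeData(nodes)
  if (nrow(nd) == 0) stop("empty NodeTable")
  # all neighbor pairs within dMax
  d2 <- outer(nd$x, nd$x, "-")^2 + outer(nd$y, nd$y, "-")^2
  hit <- which(d2 < dMax^2 & upper.tri(d2), arr.ind = TRUE)
  if (nrow(hit) == 0) {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0))
  } else {
    i <- hit[, 1]; j <- hit[, 2]
    zi <- nd$z[i]; zj <- nd$z[j]
    idi <- nd$node_id[i]; idj <- nd$node_id[j]
    # orient low z -> high z; ties by node_id
    fwd <- zi < zj | (zi == zj & idi < idj)
    edges <- data.frame(from = ifelse(fwd, idi, idj),
                        to = ifelse(fwd, idj, idi),
                        weight = abs(zj - zi), stringsAsFactors = FALSE)
  }
  new("TrailGraph", nodes = nodes, edges = edges, dMax = dMax)
}

#' Candidate start and end nodes
#'
#' Ranks nodes by exhaustion score and takes the lowest-scoring
#' \code{floor(frac * n)} nodes as potential trail starts and the
#' highest-scoring \code{floor(frac * n)} as potential ends (default: the
#' first and last 33\%). Ties are broken by node_id.
#'
#' @param nodes a \linkS4class{NodeTable} (>= 3 nodes).
#' @param frac proportion in (0, 0.5].
#' @return List with character vectors \code{starts} and \code{ends}.
#' @export
candidateEndpoints <- function(nodes, frac = 0.33) {
  if (frac <= 0 || frac > 0.5) stop("frac must be in (0, 0.5]")
  nd <- nodeData(nodes)
  if (nrow(nd) < 3) stop("need at least 3 nodes")
  m <- max(1L, floor(frac * nrow(nd)))
  lo <- order(nd$z, nd$node_id)
  hi <- order(-nd$z, nd$node_id)
  list(starts = nd$node_id[lo[seq_len(m)]],
       ends = nd$node_id[hi[seq_len(m)]])
}

# forward adjacency lists (by node index) for a TrailGraph
.adjacency <- function(g) {
  nd <- nodeData(graphNodes(g))
  n <- nrow(nd)
  idx <- stats::setNames(seq_len(n), nd$node_id)
  e <- trailEdges(g)
  adjTo <- vector("list", n)
  adjW <- vector("list", n)
  if (nrow(e)) {
    fi <- idx[e$from]
    sp <- split(seq_len(nrow(e)), fi)
    for (nm in names(sp)) {
      u <- as.integer(nm)
      adjTo[[u]] <- unname(idx[e$to[sp[[nm]]]])
      adjW[[u]] <- e$weight[sp[[nm]]]
    }
  }
  list(to = adjTo, w = adjW, ids = nd$node_id, idx = idx)
}

# single-source Dijkstra with deterministic (dist, hops, node_id) tie-breaks
.dijkstraSS <- function(adj, s) {
  n <- length(adj$ids)
  dist <- rep(Inf, n); hops <- rep(Inf, n)
  pred <- rep(NA_integer_, n); done <- rep(FALSE, n)
  dist[s] <- 0; hops[s] <- 0
  repeat {
    open <- which(!done & is.finite(dist))
    if (!length(open)) break
    cand <- open[dist[open] == min(dist[open])]
    if (length(cand) > 1) cand <- cand[hops[cand] == min(hops[cand])]
    if (length(cand) > 1) cand <- cand[order(adj$ids[cand])]
    u <- cand[1]
    done[u] <- TRUE
    vs <- adj$to[[u]]
    if (is.null(vs)) next
    nd <- dist[u] + adj$w[[u]]
    nh <- hops[u] + 1
    for (k in seq_along(vs)) {
      v <- vs[k]
      if (done[v]) next
      if (nd[k] < dist[v] ||
          (nd[k] == dist[v] &&
           (nh < hops[v] ||
            (nh == hops[v] && !is.na(pred[v]) &&
             adj$ids[u] < adj$ids[pred[v]])))) {
        dist[v] <- nd[k]; hops[v] <- nh; pred[v] <- u
      }
    }
  }
  list(dist = dist, hops = hops, pred = pred)
}

.tracePath <- function(pred, s, e) {
  path <- e
  while (path[1] != s) {
    p <- pred[path[1]]
    if (is.na(p)) return(NULL)
    path <- c(p, path)
  }
  path
}

#' Minimum-weight spanning path between two nodes
#'
#' Runs Dijkstra's algorithm on the directed exhaustion-ascent graph and
#' returns the minimum-total-weight path from \code{s} to \code{e}, i.e. the
#' route with the most gradual stepwise increases in exhaustion score. Ties
#' are broken deterministically: fewer nodes first, then lexicographically
#' smaller node ids.
#'
#' @param g a \linkS4class{TrailGraph}.
#' @param s,e start and end node ids.
#' @return A \linkS4class{Trail} with method \code{"dijkstra"}, or
#'   \code{NULL} when \code{e} is unreachable from \code{s}.
#' @export
dijkstraTrail <- function(g, s, e) {
  adj <- .adjacency(g)
  if (!s %in% adj$ids || !e %in% adj$ids) stop("unknown node id")
  si <- adj$idx[[s]]; ei <- adj$idx[[e]]
  res <- .dijkstraSS(adj, si)
  if (!is.finite(res$dist[ei])) return(NULL)
  path <- .tracePath(res$pred, si, ei)
  if (is.null(path)) return(NULL)
  Trail(adj$ids[path], graphNodes(g), method = "dijkstra")
}

#' Filter trails on length and span
#'
#' Keeps trails with at least \code{minNodes} nodes and a start-to-end 2D
#' distance of at least \code{minSpan} microns.
#'
#' @param trails list of \linkS4class{Trail}s.
#' @param minNodes minimum trail length in nodes (default 6).
#' @param minSpan minimum start-to-end distance in microns (default 500).
#' @return Filtered list.
#' @export
filterTrails <- function(trails, minNodes = 6, minSpan = 500) {
  Filter(function(tr) length(tr) >= minNodes && trailSpan(tr) >= minSpan,
         trails)
}

# affine rescale of xy onto the z range
.rescaleXY <- function(nd) {
  zr <- range(nd$z)
  resc <- function(v) {
    r <- range(v)
    if (diff(r) == 0) rep(zr[1], length(v))
    else (v - r[1]) / diff(r) * diff(zr) + zr[1]
  }
  cbind(x = resc(nd$x), y = resc(nd$y), z = nd$z)
}

#' Trails by proximity to a line in (x, y, z) space
#'
#' The 3D-line method relaxes strict score monotonicity: after rescaling the
#' xy coordinates affinely onto the range of the exhaustion score z, a
#' straight 3D segment is drawn between each admissible start/end pair and
#' every node within \code{distCutoff} (perpendicular point-to-segment
#' distance) is collected. Nodes are ordered by their scalar projection onto
#' the segment, starting from the lower-score end. A candidate is rejected
#' if any consecutive pair is farther than \code{dMax} apart in 2D, if it
#' has fewer than \code{minNodes} nodes, spans less than \code{minSpan}
#' microns, or if the score drops by more than \code{drawbackTol} between
#' any consecutive pair (small fluctuations are allowed, large drawbacks are
#' not).
#'
#' @param nodes a \linkS4class{NodeTable} with a positive score range.
#' @param starts,ends candidate endpoint ids
#'   (\code{\link{candidateEndpoints}}).
#' @param distCutoff distance cutoff in rescaled units; default 5\% of the
#'   score range.
#' @param dMax 2D adjacency threshold in microns (default 130).
#' @param drawbackTol maximum tolerated consecutive score drop; default 10\%
#'   of each trail's own score span.
#' @param minNodes,minSpan trail filters as in \code{\link{filterTrails}}.
#' @return List of \linkS4class{Trail}s with method \code{"line3d"}.
#' @export
line3dTrails <- function(nodes, starts, ends, distCutoff = NULL, dMax = 130,
                         drawbackTol = NULL, minNodes = 6, minSpan = 500) {
  nd <- nodeData(nodes)
  if (diff(range(nd$z)) <= 0) stop("z range must be positive")
  if (!is.null(distCutoff) && distCutoff <= 0)
    stop("distCutoff must be positive")
  if (is.null(distCutoff)) distCutoff <- 0.05 * diff(range(nd$z))
  P <- .rescaleXY(nd)
  idx <- stats::setNames(seq_len(nrow(nd)), nd$node_id)
  out <- list()
  for (s in starts) {
    si <- idx[[s]]
    for (e in ends) {
      if (e == s) next
      ei <- idx[[e]]
      span <- sqrt((nd$x[ei] - nd$x[si])^2 + (nd$y[ei] - nd$y[si])^2)
      if (span < minSpan) next
      # orient the segment from the lower-z end
      a <- if (nd$z[si] <= nd$z[ei]) si else ei
      b <- if (a == si) ei else si
      v <- P[b, ] - P[a, ]
      L2 <- sum(v^2)
      if (L2 == 0) next
      t <- ((P[, 1] - P[a, 1]) * v[1] + (P[, 2] - P[a, 2]) * v[2] +
              (P[, 3] - P[a, 3]) * v[3]) / L2
      tc <- pmin(pmax(t, 0), 1)
      dx <- P[, 1] - (P[a, 1] + tc * v[1])
      dy <- P[, 2] - (P[a, 2] + tc * v[2])
      dz <- P[, 3] - (P[a, 3] + tc * v[3])
      keep <- which(sqrt(dx^2 + dy^2 + dz^2) <= distCutoff)
      if (length(keep) < minNodes) next
      keep <- keep[order(t[keep], nd$node_id[keep])]
      zs <- nd$z[keep]
      tol <- if (is.null(drawbackTol)) 0.1 * diff(range(zs)) else drawbackTol
      if (any(diff(zs) < -tol)) next
      step <- sqrt(diff(nd$x[keep])^2 + diff(nd$y[keep])^2)
      if (any(step > dMax)) next
      tr <- Trail(nd$node_id[keep], nodes, method = "line3d")
      if (trailSpan(tr) < minSpan) next
      out[[length(out) + 1L]] <- tr
    }
  }
  out
}

#' Find all candidate migration trails
#'
#' Runs both trail-identification methods over every admissible start/end
#' pair (pairs closer than \code{minSpan} are skipped up front), applies the
#' length/span filters, and deduplicates identical node sequences, recording
#' both method tags when the two methods agree.
#'
#' @param g a \linkS4class{TrailGraph}.
#' @param frac endpoint quantile proportion (default 0.33).
#' @param minNodes,minSpan trail filters (defaults 6 nodes, 500 um).
#' @param distCutoff,drawbackTol 3D-line parameters
#'   (\code{\link{line3dTrails}}).
#' @param methods which methods to run (default both).
#' @return List of candidate \linkS4class{Trail}s.
#' @export
findCandidateTrails <- function(g, frac = 0.33, minNodes = 6, minSpan = 500,
                                distCutoff = NULL, drawbackTol = NULL,
                                methods = c("dijkstra", "line3d")) {
  nodes <- graphNodes(g)
  nd <- nodeData(nodes)
  ep <- candidateEndpoints(nodes, frac)
  idx <- stats::setNames(seq_len(nrow(nd)), nd$node_id)
  trails <- list()
  if ("dijkstra" %in% methods) {
    adj <- .adjacency(g)
    for (s in ep$starts) {
      si <- idx[[s]]
      endI <- idx[ep$ends[ep$ends != s]]
      span <- sqrt((nd$x[endI] - nd$x[si])^2 + (nd$y[endI] - nd$y[si])^2)
      endI <- endI[span >= minSpan]
      if (!length(endI)) next
      res <- .dijkstraSS(adj, si)
      for (ei in endI[is.finite(res$dist[endI])]) {
        path <- .tracePath(res$pred, si, ei)
        if (is.null(path) || length(path) < minNodes) next
        trails[[length(trails) + 1L]] <-
          Trail(nd$node_id[path], nodes, method = "dijkstra")
      }
    }
  }
  if ("line3d" %in% methods && diff(range(nd$z)) > 0) {
    trails <- c(trails,
                line3dTrails(nodes, ep$starts, ep$ends,
                             distCutoff = distCutoff, dMax = g@dMax,
                             drawbackTol = drawbackTol,
                             minNodes = minNodes, minSpan = minSpan))
  }
  trails <- filterTrails(trails, minNodes, minSpan)
  # deduplicate identical node sequences, merging method tags
  key <- vapply(trails, function(tr) paste(trailNodes(tr), collapse = ">"),
                character(1))
  out <- list()
  for (i in seq_along(trails)) {
    k <- key[i]
    if (is.null(out[[k]])) out[[k]] <- trails[[i]]
    else out[[k]]@method <- union(out[[k]]@method, trails[[i]]@method)
  }
  unname(out)
}
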