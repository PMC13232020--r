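#' Cluster spots by expression
#'
#' Standard expression clustering used to match control trails to real
#' trails: log1p-transformed normalized expression over the variable genes
#' is reduced by PCA and partitioned by k-means (6 clusters by default).
#' Deterministic given \code{seed}.
#'
#' @param mat gene x spot normalized matrix restricted to variable genes.
#' @param k number of clusters (default 6).
#' @param nPcs number of principal components (default 30, capped).
#' @param seed RNG seed for k-means initialization.
#' @return Integer cluster labels (1..k) named by spot.
#' @export
clusterSpots <- function(mat, k = 6, nPcs = 30, seed = 1) {
  if (k < 2) stop("k must be at least 2")
  if (ncol(mat) < k) stop("need at least k spots")
  x <- t(log1p(as.matrix(mat)))
  x <- x[, apply(x, 2, stats::sd) > 0, drop = FALSE]
  nPcs <- min(nPcs, ncol(x), nrow(x) - 1)
  pcs <- stats::prcomp(x, center = TRUE, scale. = FALSE)$x[, seq_len(nPcs),
                                                           drop = FALSE]
  km <- withSeed(seed, stats::kmeans(pcs, centers = k, nstart = 10,
                                     iter.max = 50))
  stats::setNames(as.integer(km$cluster), colnames(mat))
}

# majority cluster of a trail's member spots
.trailCluster <- function(trail, nodes, labels) {
  spots <- unlist(nodeMembers(nodes)[trailNodes(trail)], use.names = FALSE)
  tab <- sort(table(labels[spots]), decreasing = TRUE)
  as.integer(names(tab)[1])
}

#' Sample one matched control trail
#'
#' Self-avoiding random walk on the undirected T-node adjacency graph,
#' confined to nodes in the matched trail's (majority) expression cluster,
#' of exactly the trail's length, with consecutive nodes adjacent, a
#' start-to-end span of at least \code{minSpan} (0.5 mm by default), and a
#' node sequence different from the trail's own. No score-monotonicity
#' requirement.
#'
#' @param trail the matched \linkS4class{Trail}.
#' @param labels spot cluster labels (\code{\link{clusterSpots}}).
#' @param g a \linkS4class{TrailGraph} over the T nodes.
#' @param minSpan minimum start-to-end distance in microns (default 500).
#' @param maxAttempts walk restarts before giving up (default 500).
#' @param seed RNG seed, or NULL to draw from the current stream.
#' @return Character vector of node ids, or \code{NULL} on failure.
#' @export
sampleControlTrail <- function(trail, labels, g, minSpan = 500,
                               maxAttempts = 500, seed = NULL) {
  nodes <- graphNodes(g)
  nd <- nodeData(nodes)
  cl <- .trailCluster(trail, nodes, labels)
  nodeLabel <- vapply(nodeIds(nodes), function(id) {
    tab <- sort(table(labels[nodeMembers(nodes)[[id]]]), decreasing = TRUE)
    as.integer(names(tab)[1])
  }, integer(1))
  eligible <- which(nodeLabel == cl)
  len <- length(trail)
  if (length(eligible) < len) return(NULL)
  und <- .undirectedAdjacency(g)
  inCluster <- rep(FALSE, length(und$ids))
  inCluster[eligible] <- TRUE
  trailKey <- paste(trailNodes(trail), collapse = ">")
  withSeed(seed, {
    for (att in seq_len(maxAttempts)) {
      path <- eligible[sample.int(length(eligible), 1)]
      visited <- rep(FALSE, length(und$ids))
      visited[path] <- TRUE
      while (length(path) < len) {
        nb <- und$adj[[path[length(path)]]]
        nb <- nb[!visited[nb] & inCluster[nb]]
        if (length(nb) == 0) break
        v <- if (length(nb) == 1) nb else nb[sample.int(length(nb), 1)]
        visited[v] <- TRUE
        path <- c(path, v)
      }
      if (length(path) < len) next
      span <- sqrt((nd$x[path[len]] - nd$x[path[1]])^2 +
                     (nd$y[path[len]] - nd$y[path[1]])^2)
      if (span < minSpan) next
      ids <- und$ids[path]
      if (paste(ids, collapse = ">") == trailKey) next
      return(ids)
    }
    NULL
  })
}

#' Generate matched control trail sets
#'
#' For each real trail one matched control trail is sampled
#' (\code{\link{sampleControlTrail}}); the resulting list of \code{n}
#' controls is one control set, and \code{nSets} such sets (5000 by default,
#' as used for the permutation null) are generated reproducibly from
#' \code{seed}. A trail whose control cannot be sampled after repeated
#' fresh attempts raises an error naming the trail.
#'
#' @param trails list of final \linkS4class{Trail}s.
#' @param labels spot cluster labels.
#' @param g a \linkS4class{TrailGraph}.
#' @param nSets number of control sets (default 5000).
#' @param minSpan minimum control span in microns (default 500).
#' @param maxAttempts walk restarts per control (default 500).
#' @param seed RNG seed.
#' @return List of \code{nSets} sets; each set is a list of node-id vectors
#'   parallel to \code{trails}.
#' @export
generateControlSets <- function(trails, labels, g, nSets = 5000,
                                minSpan = 500, maxAttempts = 500, seed = 1) {
  if (length(trails) == 0) stop("no trails to match")
  withSeed(seed, {
    lapply(seq_len(nSets), function(si) {
      lapply(seq_along(trails), function(ti) {
        for (round in 1:3) {
          ctl <- sampleControlTrail(trails[[ti]], labels, g,
                                    minSpan = minSpan,
                                    maxAttempts = maxAttempts, seed = NULL)
          if (!is.null(ctl)) return(ctl)
        }
        stop("could not generate a matched control for trail ", ti,
             " (start ", trailNodes(trails[[ti]])[1],
             "): too few eligible cluster T spots")
      })
    })
  })
}

#' Two-sided empirical p-value
#'
#' Plain-proportion convention: \code{p = min(1, 2 * min(#\{null >= obs\},
#' #\{null <= obs\}) / n)}, so p = 0 is attainable when the observed value
#' lies outside the whole null distribution. Set
#' \code{convention = "add_one"} for the (count+1)/(n+1) variant.
#'
#' @param observed observed statistic (scalar).
#' @param nullValues vector of null statistics (one per control set).
#' @param convention \code{"plain"} (default) or \code{"add_one"}.
#' @return p-value in [0, 1].
#' @examples
#' empiricalP(3.5, c(1, 2, 3, 4))  # 0.5
#' @export
empiricalP <- function(observed, nullValues,
                       convention = c("plain", "add_one")) {
  convention <- match.arg(convention)
  if (length(nullValues) == 0) stop("empty null distribution")
  n <- length(nullValues)
  ge <- sum(nullValues >= observed)
  le <- sum(nullValues <= observed)
  if (convention == "plain") min(1, 2 * min(ge, le) / n)
  else min(1, 2 * (min(ge, le) + 1) / (n + 1))
}

#' Validate a control trail against its matching constraints
#'
#' Checks the five matching constraints: same length as the matched trail,
#' all nodes in the trail's majority cluster, consecutive adjacency below
#' \code{dMax}, membership in the T-node set, and start-to-end span of at
#' least \code{minSpan}; plus the exclusion of the trail's own sequence.
#'
#' @param control node-id vector.
#' @param trail the matched \linkS4class{Trail}.
#' @param labels spot cluster labels.
#' @param g the \linkS4class{TrailGraph}.
#' @param minSpan minimum span in microns (default 500).
#' @return TRUE or a string naming the violated constraint.
#' @export
validateControl <- function(control, trail, labels, g, minSpan = 500) {
  nodes <- graphNodes(g)
  nd <- nodeData(nodes)
  if (length(control) != length(trail)) return("length mismatch")
  i <- match(control, nd$node_id)
  if (anyNA(i)) return("node not a T node")
  cl <- .trailCluster(trail, nodes, labels)
  lab <- vapply(control, function(id) {
    tab <- sort(table(labels[nodeMembers(nodes)[[id]]]), decreasing = TRUE)
    as.integer(names(tab)[1])
  }, integer(1))
  if (!all(lab == cl)) return("node outside the trail's cluster")
  if (anyDuplicated(control)) return("repeated node")
  d <- sqrt(diff(nd$x[i])^2 + diff(nd$y[i])^2)
  if (any(d >= g@dMax)) return("consecutive nodes not adjacent")
  n <- length(i)
  span <- sqrt((nd$x[i[n]] - nd$x[i[1]])^2 + (nd$y[i[n]] - nd$y[i[1]])^2)
  if (span < minSpan) return("span too short")
  if (identical(as.character(control), trailNodes(trail)))
    return("identical to the matched trail")
  TRUE
}
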