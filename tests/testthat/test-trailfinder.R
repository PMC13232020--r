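test_that("graph edges follow the distance and direction rules", {
  nt <- NodeTable(data.frame(node_id = c("a", "b"),
                             x = c(0, 110), y = c(0, 0),
                             z = c(0.2, 0.5) - 0.2,
                             t_marker_sum = 1, umi_total = 1))
  g <- buildTrailGraph(nt, dMax = 130)
  e <- trailEdges(g)
  expect_equal(nrow(e), 1)
  expect_equal(e$from, "a")
  expect_equal(e$to, "b")
  expect_equal(e$weight, 0.3, tolerance = 1e-12)
  # beyond the threshold: no edge
  nt2 <- NodeTable(data.frame(node_id = c("a", "b"),
                              x = c(0, 200), y = c(0, 0), z = c(0, 0.3),
                              t_marker_sum = 1, umi_total = 1))
  expect_equal(nrow(trailEdges(buildTrailGraph(nt2))), 0)
  expect_error(buildTrailGraph(nt, dMax = 0), "positive")
})

test_that("graph construction matches a brute-force all-pairs oracle", {
  nt <- randomNodes(25, box = 500, seed = 7)
  g <- buildTrailGraph(nt, dMax = 130)
  e <- trailEdges(g)
  nd <- nodeData(nt)
  expected <- 0L
  for (i in 1:24) for (j in (i + 1):25) {
    d <- sqrt((nd$x[i] - nd$x[j])^2 + (nd$y[i] - nd$y[j])^2)
    if (d >= 130) next
    expected <- expected + 1L
    lo <- if (nd$z[i] < nd$z[j]) i else j
    hi <- if (lo == i) j else i
    row <- e[e$from == nd$node_id[lo] & e$to == nd$node_id[hi], ]
    expect_equal(nrow(row), 1)
    expect_equal(row$weight, abs(nd$z[i] - nd$z[j]), tolerance = 1e-12)
  }
  expect_equal(nrow(e), expected)
  expect_true(all(e$weight >= 0))
})

test_that("candidate endpoints are the z-quantile extremes", {
  nt3 <- NodeTable(data.frame(node_id = c("a", "b", "c"),
                              x = c(0, 110, 220), y = 0, z = c(0, 0.4, 0.9),
                              t_marker_sum = 1, umi_total = 1))
  ep <- candidateEndpoints(nt3)
  expect_equal(ep$starts, "a")
  expect_equal(ep$ends, "c")
  # n = 100, frac 0.33 -> 33 each; membership matches a sort oracle
  nt100 <- randomNodes(100, seed = 8)
  ep100 <- candidateEndpoints(nt100, 0.33)
  expect_length(ep100$starts, 33)
  expect_length(ep100$ends, 33)
  nd <- nodeData(nt100)
  ord <- nd$node_id[order(nd$z, nd$node_id)]
  expect_setequal(ep100$starts, head(ord, 33))
  expect_setequal(ep100$ends, tail(ord, 33))
  expect_length(intersect(ep100$starts, ep100$ends), 0)
  expect_error(candidateEndpoints(nt100, 0.6), "frac")
  expect_error(candidateEndpoints(nt100, 0), "frac")
})

test_that("Dijkstra on a monotone chain returns the chain itself", {
  n <- 7
  nt <- NodeTable(data.frame(node_id = sprintf("c%d", 1:n),
                             x = (1:n) * 110, y = 0,
                             z = seq(0, 0.9, length.out = n),
                             t_marker_sum = 1, umi_total = 1))
  g <- buildTrailGraph(nt)
  tr <- dijkstraTrail(g, "c1", "c7")
  expect_equal(trailNodes(tr), sprintf("c%d", 1:7))
  expect_equal(sum(diff(trailZ(tr))), 0.9, tolerance = 1e-12)
  expect_equal(trailMethod(tr), "dijkstra")
  # reversed endpoints are unreachable in the directed graph
  expect_null(dijkstraTrail(g, "c7", "c1"))
})

test_that("Dijkstra equals exhaustive path enumeration on random layouts", {
  # property: 200 random graphs with <= 12 nodes
  checked <- 0
  for (s in 1:200) {
    n <- sample(5:12, 1)
    nt <- randomNodes(n, box = 260, seed = 1000 + s)
    g <- buildTrailGraph(nt, dMax = 130)
    e <- trailEdges(g)
    if (nrow(e) == 0) next
    nd <- nodeData(nt)
    z <- setNames(nd$z, nd$node_id)
    se <- withSeed(2000 + s, sample(nd$node_id, 2))
    paths <- enumeratePaths(e, se[1], se[2])
    tr <- dijkstraTrail(g, se[1], se[2])
    if (length(paths) == 0) {
      expect_null(tr)
    } else {
      checked <- checked + 1
      best <- min(vapply(paths, pathWeight, numeric(1), z = z))
      expect_equal(sum(diff(trailZ(tr))), best, tolerance = 1e-9)
      # non-decreasing score along any returned trail
      expect_true(all(diff(trailZ(tr)) >= -1e-12))
    }
  }
  expect_gt(checked, 30)
})

test_that("trail filtering enforces length and span", {
  nt <- NodeTable(data.frame(node_id = sprintf("c%d", 1:8),
                             x = (1:8) * 110, y = 0,
                             z = seq(0, 1, length.out = 8),
                             t_marker_sum = 1, umi_total = 1))
  t4 <- Trail(sprintf("c%d", 1:4), nt, "dijkstra")   # short + 330 um span
  t6 <- Trail(sprintf("c%d", 1:6), nt, "dijkstra")   # 550 um span
  t8 <- Trail(sprintf("c%d", 1:8), nt, "dijkstra")
  kept <- filterTrails(list(t4, t6, t8))
  expect_length(kept, 2)
  # span 440 um removed even with enough nodes (6 nodes, min_span 500)
  ntc <- NodeTable(data.frame(node_id = sprintf("k%d", 1:6),
                              x = c(0, 110, 220, 330, 440, 440),
                              y = c(0, 0, 0, 0, 0, 110),
                              z = seq(0, 1, length.out = 6),
                              t_marker_sum = 1, umi_total = 1))
  tc <- Trail(sprintf("k%d", 1:6), ntc, "dijkstra")
  expect_lt(trailSpan(tc), 500)
  expect_length(filterTrails(list(tc)), 0)
  # brute-force predicate oracle on a random mix
  trails <- list(t4, t6, t8, tc)
  oracle <- Filter(function(tr) length(tr) >= 6 && trailSpan(tr) >= 500,
                   trails)
  expect_equal(filterTrails(trails), oracle)
})

test_that("collinear nodes are returned in projection order by line3d", {
  n <- 7
  nt <- NodeTable(data.frame(node_id = sprintf("c%d", 1:n),
                             x = (1:n) * 110, y = (1:n) * 0,
                             z = seq(0, 1, length.out = n),
                             t_marker_sum = 1, umi_total = 1))
  trs <- line3dTrails(nt, "c1", "c7", distCutoff = 1e-6)
  expect_length(trs, 1)
  expect_equal(trailNodes(trs[[1]]), sprintf("c%d", 1:7))
  expect_equal(trailMethod(trs[[1]]), "line3d")
})

test_that("line3d membership matches an independent point-to-segment oracle", {
  for (s in 1:100) {
    nt <- randomNodes(15, box = 2000, seed = 3000 + s)
    nd <- nodeData(nt)
    cutoff <- 0.25 * diff(range(nd$z))
    # oracle: rescale, measure all distances, order by projection
    zr <- range(nd$z)
    resc <- function(v) (v - min(v)) / diff(range(v)) * diff(zr) + zr[1]
    P <- cbind(resc(nd$x), resc(nd$y), nd$z)
    io <- order(nd$z)
    a <- P[io[1], ]; b <- P[io[nrow(nd)], ]
    dists <- apply(P, 1, segDist3, a = a, b = b)
    keep <- which(dists <= cutoff)
    t <- apply(P, 1, function(p) sum((p - a) * (b - a)) / sum((b - a)^2))
    oracleOrder <- nd$node_id[keep[order(t[keep], nd$node_id[keep])]]
    trs <- line3dTrails(nt, nd$node_id[io[1]], nd$node_id[io[nrow(nd)]],
                        distCutoff = cutoff, dMax = 1e9,
                        drawbackTol = Inf, minNodes = 2, minSpan = 0)
    expect_length(trs, 1)
    expect_equal(trailNodes(trs[[1]]), oracleOrder)
  }
})

test_that("line3d rejects large score drawbacks and non-adjacent steps", {
  n <- 7
  z <- seq(0, 1, length.out = n)
  z[5] <- z[4] - 0.1   # score drops by 0.1 between consecutive nodes
  nt <- NodeTable(data.frame(node_id = sprintf("c%d", 1:n),
                             x = (1:n) * 110, y = 0, z = z,
                             t_marker_sum = 1, umi_total = 1))
  expect_length(line3dTrails(nt, "c1", "c7", distCutoff = 10,
                             drawbackTol = 0.05), 0)
  # same geometry, tolerant drawback: accepted in original order
  ok <- line3dTrails(nt, "c1", "c7", distCutoff = 10, drawbackTol = 0.2)
  expect_length(ok, 1)
  expect_equal(trailNodes(ok[[1]]), sprintf("c%d", 1:7))
  # a spatial gap along the route is rejected
  nt2 <- NodeTable(data.frame(node_id = sprintf("g%d", 1:6),
                              x = c(0, 110, 220, 500, 610, 720), y = 0,
                              z = seq(0, 1, length.out = 6),
                              t_marker_sum = 1, umi_total = 1))
  expect_length(line3dTrails(nt2, "g1", "g6", distCutoff = 10), 0)
  expect_error(line3dTrails(nt, "c1", "c7", distCutoff = 0), "positive")
})

test_that("line3d is invariant to xy translation and node relabeling", {
  nt <- randomNodes(20, box = 1500, seed = 77)
  nd <- nodeData(nt)
  io <- order(nd$z)
  s <- nd$node_id[io[1]]; e <- nd$node_id[io[20]]
  t1 <- line3dTrails(nt, s, e, distCutoff = 0.3 * diff(range(nd$z)),
                     dMax = 1e9, drawbackTol = Inf, minNodes = 2,
                     minSpan = 0)
  ndT <- nd
  ndT$x <- ndT$x + 5000; ndT$y <- ndT$y - 3000
  t2 <- line3dTrails(NodeTable(ndT), s, e,
                     distCutoff = 0.3 * diff(range(nd$z)), dMax = 1e9,
                     drawbackTol = Inf, minNodes = 2, minSpan = 0)
  expect_equal(trailNodes(t1[[1]]), trailNodes(t2[[1]]))
})

test_that("candidate search finds planted chains and deduplicates", {
  # a slide with one planted monotone chain of 8 adjacent T nodes
  sl <- plantedSlide(seed = 202, nTrails = 1, rows = 20, cols = 20)
  cands <- findCandidateTrails(sl$graph)
  expect_gt(length(cands), 0)
  planted <- sl$sim$truth$trails[[1]]
  best <- max(vapply(cands, function(tr)
    jaccardNodes(trailNodes(tr), planted), numeric(1)))
  expect_gte(best, 0.6)
  # no admissible pair: tiny layout below the span threshold
  ntS <- NodeTable(data.frame(node_id = c("a", "b", "c"),
                              x = c(0, 110, 220), y = 0, z = c(0, 0.5, 1),
                              t_marker_sum = 1, umi_total = 1))
  expect_length(findCandidateTrails(buildTrailGraph(ntS)), 0)
  # duplicates: identical node sequences carry merged method tags
  keys <- vapply(cands, function(tr)
    paste(trailNodes(tr), collapse = ">"), character(1))
  expect_false(anyDuplicated(keys) > 0)
  # every emitted trail passes the shared validator
  for (tr in cands)
    expect_true(isTRUE(validateTrail(tr, graphNodes(sl$graph))))
})
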