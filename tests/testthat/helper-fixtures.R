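# shared fixtures and independent oracles

jaccardNodes <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# minimal STDataset: given named count matrix and coordinates
makeDs <- function(counts, xy, platform = "visium", pitch = 110) {
  STDataset(Matrix::Matrix(counts, sparse = TRUE), xy,
            platform = platform, pitch_um = pitch)
}

# random NodeTable on a box, z iid uniform, min shifted to 0
randomNodes <- function(n, box = 400, seed = 1) {
  withSeed(seed, {
    z <- stats::runif(n)
    NodeTable(data.frame(
      node_id = sprintf("n%02d", seq_len(n)),
      x = stats::runif(n, 0, box), y = stats::runif(n, 0, box),
      z = z - min(z), t_marker_sum = stats::runif(n, 1, 10),
      umi_total = 1000))
  })
}

# oracle: all simple directed paths from s to e by depth-first enumeration
enumeratePaths <- function(edges, s, e) {
  adj <- split(edges$to, edges$from)
  paths <- list()
  walk <- function(path) {
    u <- path[length(path)]
    if (u == e) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (v in adj[[u]]) if (!v %in% path) walk(c(path, v))
  }
  if (s %in% names(adj) || s == e) walk(s)
  paths
}

pathWeight <- function(path, z) sum(diff(z[path]))

# oracle: point-to-segment distance in 3D
segDist3 <- function(p, a, b) {
  v <- b - a
  t <- sum((p - a) * v) / sum(v * v)
  t <- min(max(t, 0), 1)
  sqrt(sum((p - (a + t * v))^2))
}

# oracle: hand-written Benjamini-Hochberg adjustment
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# oracle: one-sided Fisher enrichment p by direct hypergeometric summation
fisherOracle <- function(a, m, N, k) {
  js <- max(0, m + k - N):min(m, k)
  js <- js[js >= a]
  sum(choose(m, js) * choose(N - m, k - js)) / choose(N, k)
}

# small planted slide shared by several heavier tests
plantedSlide <- function(seed = 101, ...) {
  sim <- simulateDataset(synthConfig(seed = seed, ...))
  ds <- normalizeCounts(sim$dataset)
  ts <- detectTSpots(ds)
  nodes <- exhaustionScore(ds, ts)
  g <- buildTrailGraph(nodes)
  list(sim = sim, ds = ds, tSpots = ts, nodes = nodes, graph = g)
}

# stage-gene machinery for a planted slide (mirrors the pipeline defaults)
stageSetup <- function(sl) {
  tpm <- tpmMatrix(sl$ds)
  sg <- selectStageGenes(tpm[, sl$tSpots, drop = FALSE],
                         defaultGenePanels()@stageGeneCandidates,
                         nodeData(sl$nodes)$t_marker_sum)
  if (length(sg) < 3)
    sg <- intersect(defaultGenePanels()@stageGeneCandidates, rownames(sl$ds))
  nodeExpression(sl$ds, sl$nodes, sg)
}
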