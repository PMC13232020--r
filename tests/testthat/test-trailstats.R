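test_that("trend test recovers an exact index effect", {
  td <- simulateTrendData(nTrails = 6, len = 7, seed = 1)
  # overwrite expression with the index itself: slope exactly 1
  idx <- rep(1:7, 6)
  td$mat[1, ] <- idx
  res <- suppressWarnings(trendTest(td$trails, td$mat, "SETGENE"))
  expect_equal(res$beta, 1, tolerance = 1e-6)
  expect_lt(res$p, 1e-10)
  expect_equal(res$n_obs, 42)
  expect_equal(res$n_trails, 6)
})

test_that("trend test recovers a known slope from a random-intercept model", {
  # generative-parameter recovery: y = 0.5*index + b_t + e
  hits <- 0
  for (r in 1:40) {
    withSeed(5000 + r, {
      nT <- 20; len <- 7
      b <- rnorm(nT, 0, 2)
      idx <- rep(1:len, nT)
      y <- 0.5 * idx + rep(b, each = len) + rnorm(nT * len, 0, 1)
    })
    td <- simulateTrendData(nTrails = nT, len = len, seed = 1)
    td$mat[1, ] <- y
    res <- trendTest(td$trails, td$mat, "SETGENE")
    ci <- res$beta + c(-1.96, 1.96) * res$se
    if (ci[1] <= 0.5 && 0.5 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 33)   # ~95% coverage over 40 replicates
})

test_that("trend test falls back to per-trail OLS on singular fits", {
  td <- simulateTrendData(nTrails = 5, len = 6, interceptSd = 0, seed = 2)
  # iid noise with zero trail-level variance: the mixed fit is singular
  # (seed chosen so the intercept variance estimate collapses to 0)
  withSeed(33, td$mat[1, ] <- rnorm(30))
  expect_message(res <- trendTest(td$trails, td$mat, "SETGENE"),
                 "falling back")
  expect_equal(res$method, "ols_fallback")
  expect_true(is.finite(res$p))
  expect_error(trendTest(td$trails[1], td$mat, "SETGENE"), "2 trails")
})

test_that("empirical DE calls planted effects and leaves constants alone", {
  sl <- plantedSlide(seed = 301)
  cands <- findCandidateTrails(sl$graph)
  trails <- cands[1:2]
  tpm <- tpmMatrix(sl$ds)
  vg <- selectVariableGenes(tpm, 60)
  labels <- clusterSpots(tpm[vg, , drop = FALSE], k = 3, seed = 5)
  sets <- generateControlSets(trails, labels, sl$graph, nSets = 100,
                              seed = 9)
  nodeTpm <- nodeExpression(sl$ds, sl$nodes, rownames(sl$ds))
  # plant: constant gene, and a 3x elevated gene on trail nodes
  onTrail <- unique(unlist(lapply(trails, trailNodes)))
  mat <- rbind(nodeTpm,
               FLATGENE = 42,
               UPGENE = ifelse(colnames(nodeTpm) %in% onTrail, 300, 100))
  de <- deTest(trails, sets, mat, c("FLATGENE", "UPGENE", vg))
  flat <- de[de$gene == "FLATGENE", ]
  expect_equal(flat$fc, 1)
  expect_equal(flat$p, 1)
  expect_equal(flat$call, "ns")
  up <- de[de$gene == "UPGENE", ]
  expect_equal(up$call, "up")
  expect_gt(up$fc, 1.2)
  expect_lt(up$p_adj, 0.05)
  # BH invariants: adjusted >= raw, monotone in rank order, <= 1
  expect_true(all(de$p_adj >= de$p - 1e-12))
  expect_true(all(de$p_adj <= 1))
  o <- order(de$p)
  expect_true(all(diff(de$p_adj[o]) >= -1e-12))
  # absent genes are skipped with a warning
  expect_warning(deTest(trails, sets, mat, c("NOPE", "UPGENE")), "absent")
})

test_that("shared V-gene statistic matches the set-intersection oracle", {
  nt <- NodeTable(data.frame(node_id = paste0("s", 1:3),
                             x = c(0, 110, 220), y = 0, z = c(0, 0.5, 1),
                             t_marker_sum = 1, umi_total = 1))
  trail <- Trail(paste0("s", 1:3), nt, "dijkstra")
  # detected V-gene sets {A,B}, {B,C}, {C}: overlaps (1, 1) -> mean 1
  cnt <- matrix(0, 3, 3, dimnames = list(c("TRAV1", "TRBV2", "TRAJ3"),
                                         paste0("s", 1:3)))
  cnt["TRAV1", 1] <- 5; cnt["TRBV2", 1] <- 1
  cnt["TRBV2", 2] <- 2; cnt["TRAJ3", 2] <- 9
  cnt["TRAJ3", 3] <- 1
  ctl <- list(list(paste0("s", c(3, 2, 1))))
  res <- sharedVgeneTest(list(trail), ctl, cnt, "^TRAV|^TRAJ|^TRBV")
  expect_equal(res$perTrail, 1)
  expect_equal(res$observed, 1)
  # magnitude invariance: only detection matters
  res2 <- sharedVgeneTest(list(trail), ctl, cnt * 100, "^TRAV|^TRAJ|^TRBV")
  expect_equal(res2$observed, res$observed)
  # all spots sharing the same 4 genes -> trail mean 4
  cnt4 <- matrix(1, 4, 3, dimnames = list(paste0("TRAV", 1:4),
                                          paste0("s", 1:3)))
  res4 <- sharedVgeneTest(list(trail), ctl, cnt4, "^TRAV")
  expect_equal(res4$observed, 4)
  expect_error(sharedVgeneTest(list(trail), ctl, cnt, "^IGHV"),
               "prefixes")
})

test_that("Fisher ORA equals hypergeometric enumeration and sorts by FDR", {
  # spot checks including the frozen table (a=3, b=2, c=1, d=14)
  expect_equal(
    oraFisher("G1", GeneSetList(list(S = "G2")),
              universe = c("G1", "G2", "G3"))$p, 1)
  uni <- sprintf("G%02d", 1:20)
  query <- uni[1:5]                      # a+b = 5 -> a=3 means b=2
  set <- uni[c(1:3, 6)]                  # m = 4, overlap a = 3
  tab <- oraFisher(query, GeneSetList(list(S = set)), universe = uni)
  expect_equal(tab$overlap, 3)
  expect_equal(tab$p, fisherOracle(3, 4, 20, 5), tolerance = 1e-12)
  expect_equal(tab$p,
               fisher.test(matrix(c(3, 2, 1, 14), 2),
                           alternative = "greater")$p.value,
               tolerance = 1e-12)
  # degenerate: universe = query = set gives the minimal achievable p
  d <- oraFisher(uni, GeneSetList(list(S = uni)), universe = uni)
  expect_equal(d$p, 1)                   # only one table is possible
  expect_error(oraFisher("G1", GeneSetList(list(S = "G1")),
                         universe = character(0)), "universe")
  expect_error(oraFisher("X", GeneSetList(list(S = "G1")), universe = uni),
               "subset")
})

test_that("phenotype ranking orders clusters by median rank", {
  set.seed(121)
  cm <- matrix(rnorm(4 * 6, 10, 2), nrow = 4,
               dimnames = list(paste0("cl", 1:4), paste0("g", 1:6)))
  pr <- phenotypeRank(paste0("g", 1:6), cm)
  # per-gene sorting oracle
  for (g in colnames(cm))
    expect_equal(unname(pr$ranks[, g]), unname(rank(cm[, g])))
  expect_equal(pr$summary$cluster,
               pr$summary$cluster[order(-pr$summary$median_rank,
                                        -pr$summary$mean_rank)])
  # a dominating cluster gets the top rank everywhere (13-cluster case)
  cm13 <- matrix(rnorm(13 * 5, 5, 1), nrow = 13,
                 dimnames = list(paste0("cl", 1:13), paste0("g", 1:5)))
  cm13["cl7", ] <- 100
  pr13 <- phenotypeRank(paste0("g", 1:5), cm13)
  expect_equal(pr13$summary$cluster[1], "cl7")
  expect_equal(pr13$summary$median_rank[1], 13)
  expect_error(phenotypeRank("nope", cm), "overlap")
})
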