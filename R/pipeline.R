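#' Pipeline run configuration
#'
#' All tunable parameters of the trail-reconstruction pipeline, with the
#' standard defaults: 130 um adjacency, 500 um minimum span, 6-node minimum
#' length, 33\% endpoint quantiles, 85th-percentile selection rule, 6
#' expression clusters, 5000 matched control sets, fold-change cut 1.2,
#' FDR cut 0.05, 3000 variable genes, HD aggregation radius 5x pitch. The
#' config is a plain serializable list, so a finished run can be reproduced
#' from its saved manifest.
#'
#' @param dMax adjacency threshold, microns.
#' @param minSpan minimum trail span, microns.
#' @param minNodes minimum trail length, nodes.
#' @param endpointFrac endpoint quantile proportion.
#' @param percentile pooled alternative-route percentile.
#' @param kClusters expression clusters for control matching.
#' @param nPcs principal components for clustering.
#' @param nControlSets matched control sets.
#' @param fcCut,fdrCut differential-expression thresholds.
#' @param nVariableGenes variable genes for clustering and DE.
#' @param radiusFactor HD aggregation radius in pitch multiples.
#' @param hdTol HD score tolerance (NULL = 5\% of score range).
#' @param kMinAlt,kMaxAlt alternative-route count bounds.
#' @param altAttempts alternative-route walk attempts per candidate.
#' @param controlAttempts control-walk restarts per control.
#' @param tThreshold T-spot raw marker-count threshold (exclusive).
#' @param distCutoff 3D-line distance cutoff (NULL = 5\% of score range).
#' @param drawbackTol 3D-line consecutive score-drop tolerance (NULL = 10\%
#'   of each trail's score span).
#' @param insufficientPolicy candidates lacking alternatives: \code{"drop"}
#'   or \code{"keep"}.
#' @param seed master RNG seed for the run.
#' @return Config list of class \code{TrailsConfig}.
#' @export
trailsConfig <- function(dMax = 130, minSpan = 500, minNodes = 6,
                         endpointFrac = 0.33, percentile = 85, kClusters = 6,
                         nPcs = 30, nControlSets = 5000, fcCut = 1.2,
                         fdrCut = 0.05, nVariableGenes = 3000,
                         radiusFactor = 5, hdTol = NULL, kMinAlt = 5,
                         kMaxAlt = 15, altAttempts = 300,
                         controlAttempts = 500, tThreshold = 0,
                         distCutoff = NULL, drawbackTol = NULL,
                         insufficientPolicy = "drop", seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "TrailsConfig"
  cfg
}

.writeTrailTable <- function(trails, nodes, path) {
  if (length(trails) == 0) {
    df <- data.frame(trail_id = integer(0), method = character(0),
                     position = integer(0), node_id = character(0),
                     x = numeric(0), y = numeric(0), z = numeric(0),
                     span_um = numeric(0))
  } else {
    nd <- nodeData(nodes)
    df <- do.call(rbind, lapply(seq_along(trails), function(k) {
      ids <- trailNodes(trails[[k]])
      i <- match(ids, nd$node_id)
      data.frame(trail_id = k,
                 method = paste(trailMethod(trails[[k]]), collapse = "+"),
                 position = seq_along(ids), node_id = ids,
                 x = nd$x[i], y = nd$y[i], z = nd$z[i],
                 span_um = trailSpan(trails[[k]]))
    }))
  }
  utils::write.csv(df, path, row.names = FALSE)
  df
}

#' Run the full trail-reconstruction pipeline
#'
#' Chains every stage: read (or accept) a slide, normalize, select variable
#' genes, detect T spots, score exhaustion (aggregating pixels into nodes
#' on Visium HD), build the ascent graph, search candidate trails with both
#' methods, select trails against alternative routes, cluster spots,
#' generate matched control sets, and run the downstream statistics
#' (chemokine/macrophage trend tests, empirical differential expression,
#' shared TCR/BCR variable genes when present, optional enrichment and
#' phenotype ranking). All outputs are written as CSV tables plus a JSON
#' run manifest; runs with identical config and input are byte-identical.
#'
#' @param input an \linkS4class{STDataset} or a directory readable by
#'   \code{\link{readVisium}}.
#' @param config a \code{\link{trailsConfig}}.
#' @param outDir output directory (created); NULL skips file output.
#' @param panels a \linkS4class{GenePanels}.
#' @param geneSetsGmt optional GMT path for over-representation analysis.
#' @param clusterMeans optional cluster x gene mean-expression matrix for
#'   phenotype ranking.
#' @param verbose emit progress messages (default TRUE).
#' @return (Invisibly) a list with the dataset, nodes, graph, candidate and
#'   final trails, control sets, and all result tables.
#' @export
runPipeline <- function(input, config = trailsConfig(), outDir = NULL,
                        panels = defaultGenePanels(), geneSetsGmt = NULL,
                        clusterMeans = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message("[", ..., "]")
  stage <- function(name, expr) {
    say(name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  ds <- stage("read", {
    if (is(input, "STDataset")) input else readVisium(input)
  })
  ds <- stage("normalize", normalizeCounts(ds))
  tpm <- tpmMatrix(ds)
  varGenes <- stage("variable_genes",
                    selectVariableGenes(tpm, min(config$nVariableGenes,
                                                 nrow(ds))))
  tSpots <- stage("detect_t_spots",
                  detectTSpots(ds, panels, threshold = config$tThreshold))
  nodes <- stage("exhaustion_score", exhaustionScore(ds, tSpots, panels))
  if (stPlatform(ds) == "visium_hd")
    nodes <- stage("hd_aggregate",
                   hdAggregate(nodes, pitchUm(ds),
                               radiusFactor = config$radiusFactor,
                               tol = config$hdTol))
  g <- stage("build_graph", buildTrailGraph(nodes, dMax = config$dMax))
  candidates <- stage("candidate_trails",
                      findCandidateTrails(g, frac = config$endpointFrac,
                                          minNodes = config$minNodes,
                                          minSpan = config$minSpan,
                                          distCutoff = config$distCutoff,
                                          drawbackTol = config$drawbackTol))
  say("candidate_trails: ", length(candidates), " candidates")

  tSum <- nodeData(nodes)$t_marker_sum[match(tSpots, nodeIds(nodes))]
  stageGenes <- stage("stage_genes", {
    sg <- selectStageGenes(tpm[, tSpots, drop = FALSE],
                           panels@stageGeneCandidates, tSum)
    if (length(sg) < 3) {
      warning("fewer than 3 stage genes selected; ",
              "using all available candidates")
      sg <- intersect(panels@stageGeneCandidates, rownames(ds))
    }
    sg
  })
  stageExpr <- nodeExpression(ds, nodes, stageGenes)
  altSets <- stage("alternative_routes",
                   lapply(seq_along(candidates), function(i)
                     sampleAlternativeRoutes(
                       g, candidates[[i]], kMin = config$kMinAlt,
                       kMax = config$kMaxAlt,
                       maxAttempts = config$altAttempts,
                       minNodes = config$minNodes,
                       seed = .childSeed(config$seed, i))))
  fin <- stage("trail_selection",
               if (length(candidates)) {
                 finalizeTrails(candidates, altSets, stageExpr,
                                percentile = config$percentile,
                                kMin = config$kMinAlt,
                                insufficientPolicy = config$insufficientPolicy)
               } else list(trails = list(), scores = numeric(0),
                           keep = logical(0), insufficient = integer(0),
                           pooledCutoff = NA_real_))
  trails <- fin$trails
  say("trail_selection: ", length(trails), " final trails")

  labels <- stage("cluster_spots",
                  clusterSpots(tpm[varGenes, , drop = FALSE],
                               k = config$kClusters, nPcs = config$nPcs,
                               seed = .childSeed(config$seed, 7001)))
  results <- list(dataset = ds, nodes = nodes, graph = g,
                  candidates = candidates, selection = fin, trails = trails,
                  stageGenes = stageGenes, labels = labels, config = config)

  if (length(trails) >= 2) {
    controls <- stage("control_sets",
                      generateControlSets(trails, labels, g,
                                          nSets = config$nControlSets,
                                          minSpan = config$minSpan,
                                          maxAttempts = config$controlAttempts,
                                          seed = .childSeed(config$seed, 7002)))
    nodeTpm <- nodeExpression(ds, nodes, varGenes)
    trend <- stage("trend_tests", {
      sets <- c(panels@chemokineSets,
                list(macrophage = panels@macrophageMarkers))
      exprAll <- nodeExpression(ds, nodes,
                                unique(c(unlist(sets), varGenes)))
      do.call(rbind, lapply(names(sets), function(nm) {
        genes <- intersect(sets[[nm]], rownames(exprAll))
        if (length(genes) == 0)
          return(NULL)
        trendTest(trails, exprAll, genes, setName = nm)
      }))
    })
    de <- stage("de_test",
                deTest(trails, controls, nodeTpm, varGenes,
                       fcCut = config$fcCut, fdrCut = config$fdrCut))
    nodeCounts <- stage("node_counts", {
      cnt <- as.matrix(assay(ds, "counts"))
      mem <- nodeMembers(nodes)
      vapply(nodeIds(nodes), function(id) {
        m <- mem[[id]]
        if (length(m) == 1) cnt[, m] else rowSums(cnt[, m, drop = FALSE])
      }, numeric(nrow(cnt)))
    })
    tcr <- if (any(grepl(panels@vgenePatterns$tcr, rownames(ds)))) {
      stage("shared_tcr",
            sharedVgeneTest(trails, controls, nodeCounts,
                            panels@vgenePatterns$tcr))
    } else NULL
    bcr <- if (any(grepl(panels@vgenePatterns$bcr, rownames(ds)))) {
      stage("shared_bcr",
            sharedVgeneTest(trails, controls, nodeCounts,
                            panels@vgenePatterns$bcr))
    } else NULL
    enr <- if (!is.null(geneSetsGmt)) {
      stage("enrichment", {
        gsl <- readGmt(geneSetsGmt)
        oraFisher(de$gene[de$call == "up"], gsl, universe = varGenes)
      })
    } else NULL
    pheno <- if (!is.null(clusterMeans) && any(de$call == "up")) {
      stage("phenotype_rank",
            phenotypeRank(de$gene[de$call == "up"], clusterMeans))
    } else NULL
    results <- c(results, list(controls = controls, trend = trend, de = de,
                               tcr = tcr, bcr = bcr, enrichment = enr,
                               phenotype = pheno))
  } else {
    say("downstream statistics skipped: fewer than 2 final trails")
  }

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    .writeTrailTable(trails, nodes, file.path(outDir, "trails.csv"))
    .writeTrailTable(candidates, nodes, file.path(outDir, "candidates.csv"))
    if (!is.null(results$de))
      utils::write.csv(results$de, file.path(outDir, "de_table.csv"),
                       row.names = FALSE)
    if (!is.null(results$trend))
      utils::write.csv(results$trend, file.path(outDir, "trend_tests.csv"),
                       row.names = FALSE)
    if (!is.null(results$enrichment))
      utils::write.csv(results$enrichment,
                       file.path(outDir, "enrichment.csv"), row.names = FALSE)
    if (!is.null(results$phenotype))
      utils::write.csv(results$phenotype$summary,
                       file.path(outDir, "phenotype_ranks.csv"),
                       row.names = FALSE)
    if (!is.null(results$controls)) {
      nCtl <- length(results$controls)
      utils::write.csv(
        data.frame(n_sets = nCtl, n_trails = length(trails)),
        file.path(outDir, "controls_summary.csv"), row.names = FALSE)
    }
    manifest <- list(
      package = "TcellTrails",
      version = as.character(utils::packageVersion("TcellTrails")),
      config = unclass(config),
      n_spots = ncol(ds), n_genes = nrow(ds),
      n_t_spots = length(tSpots), n_nodes = length(nodes),
      n_candidates = length(candidates), n_trails = length(trails))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(results)
}
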