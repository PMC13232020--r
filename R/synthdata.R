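#' Synthetic slide configuration
#'
#' Study conditions for the synthetic Visium-like generator: a hexagonal
#' lattice at the standard 110 um pitch carrying planted straight migration
#' trails with log-linear exhaustion and chemokine gradients, trail-coherent
#' stage genes, trail-shared TCR variable genes, and negative-binomial
#' counts thinned by dropout.
#'
#' @param rows,cols lattice size (default 30 x 30).
#' @param pitchUm spot pitch in microns (default 110).
#' @param nTrails planted trails (default 5).
#' @param trailLength nodes per planted trail (default 8).
#' @param exhaustionGradient log-fold increase of exhaustion-marker mean per
#'   trail step (default 0.6, a strong planted gradient: the per-step rise
#'   is several times the per-node score noise; 0 disables the gradient).
#'   Off-trail T spots sit at the mid-trail exhaustion level so trail
#'   starts rank low and trail ends rank high.
#' @param chemokineGradient log-fold increase of chemokine and macrophage
#'   marker means per trail step (default log(1.3)).
#' @param stageCoherenceSd sd of the lognormal stage-gene factors (default
#'   0.8); shared per (trail, gene) when \code{coherentStageGenes}.
#' @param coherentStageGenes share stage-gene factors along each planted
#'   trail (default TRUE; FALSE makes them per-spot, removing coherence).
#' @param tFraction fraction of off-trail spots that are T-cell infiltrated
#'   (default 0.4, a moderately-to-densely infiltrated tumor section).
#' @param nBackgroundGenes unstructured background genes (default 200).
#' @param baselineMean NB mean of background genes (default 60, giving
#'   spot libraries of roughly 12,000 UMIs).
#' @param tMarkerMean per-marker NB mean of T markers in T spots (default 10).
#' @param exhaustionMean base per-marker NB mean of exhaustion markers in T
#'   spots (default 10; together with \code{nbSize} this keeps per-node score
#'   noise well below the planted per-step gradient, i.e. decisively inside
#'   the strong-gradient regime).
#' @param stageMean base NB mean of stage genes in T spots (default 4).
#' @param chemokineMean base NB mean of chemokine/macrophage genes (default 2).
#' @param densitySd sd of the per-T-spot lognormal "T density" factor that
#'   scales T, exhaustion and stage markers jointly (default 0.1).
#' @param nbSize NB size (dispersion) parameter (default 6).
#' @param dropout independent transcript drop probability (default 0.05).
#' @param seed RNG seed.
#' @return A validated config list of class \code{SynthConfig}.
#' @export
synthConfig <- function(rows = 30, cols = 30, pitchUm = 110, nTrails = 5,
                        trailLength = 8, exhaustionGradient = 0.6,
                        chemokineGradient = log(1.3), stageCoherenceSd = 0.8,
                        coherentStageGenes = TRUE, tFraction = 0.4,
                        nBackgroundGenes = 200, baselineMean = 60,
                        tMarkerMean = 10, exhaustionMean = 10, stageMean = 4,
                        chemokineMean = 2, densitySd = 0.1, nbSize = 6,
                        dropout = 0.05, seed = 1) {
  cfg <- as.list(environment())
  rates <- c(cfg$exhaustionGradient, cfg$chemokineGradient,
             cfg$stageCoherenceSd, cfg$tFraction, cfg$baselineMean,
             cfg$tMarkerMean, cfg$exhaustionMean, cfg$stageMean,
             cfg$chemokineMean, cfg$densitySd, cfg$nbSize, cfg$dropout)
  if (any(rates < 0)) stop("all rates must be non-negative")
  if (cfg$dropout >= 1) stop("dropout must be < 1")
  if (cfg$trailLength < 2) stop("trailLength must be >= 2")
  if (cfg$trailLength > max(rows, cols))
    stop("planted trails do not fit on the grid")
  class(cfg) <- "SynthConfig"
  cfg
}

#' Hexagonal spot lattice
#'
#' Interleaved hexagonal lattice with the given center-to-center pitch:
#' x = (col + (row mod 2)/2) * pitch, y = row * pitch * sqrt(3)/2. Interior
#' spots have exactly 6 neighbors at distance \code{pitchUm}.
#'
#' @param rows,cols lattice size (>= 2 each).
#' @param pitchUm pitch in microns (default 110).
#' @return data.frame: \code{spot_id}, \code{row}, \code{col} (0-based),
#'   \code{x}, \code{y} in microns.
#' @export
makeHexGrid <- function(rows, cols, pitchUm = 110) {
  stopifnot(rows >= 2, cols >= 2)
  g <- expand.grid(col = seq_len(cols) - 1L, row = seq_len(rows) - 1L)
  data.frame(spot_id = sprintf("spot_%03d_%03d", g$row, g$col),
             row = g$row, col = g$col,
             x = (g$col + 0.5 * (g$row %% 2)) * pitchUm,
             y = g$row * pitchUm * sqrt(3) / 2,
             stringsAsFactors = FALSE)
}

# straight hex-lattice step rules: E, and the two upward diagonals
.hexStep <- function(row, col, dir) {
  switch(dir,
         e = c(row, col + 1L),
         ne = c(row + 1L, col + (row %% 2L)),
         nw = c(row + 1L, col + (row %% 2L) - 1L))
}

# plant non-overlapping straight trails; returns list of row/col matrices
.plantTrails <- function(rows, cols, nTrails, len, maxTries = 500) {
  used <- matrix(FALSE, rows, cols)
  trails <- list()
  dirs <- c("e", "ne", "nw")
  for (tryi in seq_len(maxTries)) {
    if (length(trails) == nTrails) break
    dir <- dirs[sample.int(3, 1)]
    r0 <- sample.int(rows, 1) - 1L
    c0 <- sample.int(cols, 1) - 1L
    path <- matrix(NA_integer_, len, 2)
    path[1, ] <- c(r0, c0)
    ok <- TRUE
    for (i in 2:len) {
      nxt <- .hexStep(path[i - 1, 1], path[i - 1, 2], dir)
      if (nxt[1] >= rows || nxt[2] < 0 || nxt[2] >= cols) { ok <- FALSE; break }
      path[i, ] <- nxt
    }
    if (!ok) next
    lin <- path[, 1] + 1L + path[, 2] * rows
    if (any(used[lin])) next
    used[lin] <- TRUE
    trails[[length(trails) + 1L]] <- path
  }
  if (length(trails) < nTrails)
    stop("could not place ", nTrails, " non-overlapping trails")
  trails
}

#' Simulate a Visium-like slide with planted migration trails
#'
#' Plants \code{nTrails} straight, mutually non-overlapping trails of
#' adjacent spots on the hexagonal lattice; marks trail spots plus a random
#' \code{tFraction} of the remaining spots as T-cell infiltrated; builds a
#' gene-by-spot mean matrix (T markers, exhaustion markers with a log-linear
#' gradient along trails, chemokine and macrophage panels with their own
#' gradient, trail-coherent stage genes, trail-clonal TCR variable genes and
#' unstructured background genes); draws negative-binomial counts and thins
#' them by dropout. Fully reproducible from \code{cfg$seed}.
#'
#' @param cfg a \code{\link{synthConfig}}.
#' @return List with \code{dataset} (an \linkS4class{STDataset}) and
#'   \code{truth}: planted trail spot sequences, true T spots, the per-gene
#'   planted effect table and the lattice.
#' @export
simulateDataset <- function(cfg = synthConfig()) {
  stopifnot(inherits(cfg, "SynthConfig"))
  panels <- defaultGenePanels()
  withSeed(cfg$seed, {
    grid <- makeHexGrid(cfg$rows, cfg$cols, cfg$pitchUm)
    paths <- .plantTrails(cfg$rows, cfg$cols, cfg$nTrails, cfg$trailLength)
    key <- paste(grid$row, grid$col)
    trailSpots <- lapply(paths, function(p)
      grid$spot_id[match(paste(p[, 1], p[, 2]), key)])
    onTrail <- unlist(trailSpots, use.names = FALSE)
    others <- setdiff(grid$spot_id, onTrail)
    tOff <- others[stats::runif(length(others)) < cfg$tFraction]
    tSpots <- c(onTrail, tOff)
    nSpot <- nrow(grid)
    spotIds <- grid$spot_id
    isT <- spotIds %in% tSpots
    # per-T-spot density factor (number of T cells proxy)
    dens <- rep(1, nSpot)
    dens[isT] <- exp(stats::rnorm(sum(isT), 0, cfg$densitySd))
    # trail index per spot (0 = off trail)
    tIndex <- rep(0L, nSpot)
    tId <- rep(0L, nSpot)
    for (k in seq_along(trailSpots)) {
      i <- match(trailSpots[[k]], spotIds)
      tIndex[i] <- seq_along(i)
      tId[i] <- k
    }
    midMult <- exp(cfg$exhaustionGradient * (cfg$trailLength - 1) / 2)
    exMult <- ifelse(tIndex > 0,
                     exp(cfg$exhaustionGradient * (tIndex - 1)),
                     ifelse(isT, midMult, 1))
    chemoMult <- ifelse(tIndex > 0,
                        exp(cfg$chemokineGradient * (tIndex - 1)), 1)

    genes <- list()
    lowBg <- 0      # immune transcripts absent outside infiltrated spots
    addGene <- function(name, mu) genes[[name]] <<- mu
    for (g in panels@tMarkers)
      addGene(g, ifelse(isT, cfg$tMarkerMean * dens, lowBg))
    for (g in panels@exhaustionMarkers)
      addGene(g, ifelse(isT, cfg$exhaustionMean * dens * exMult, lowBg))
    chemoGenes <- unique(unlist(panels@chemokineSets))
    for (g in c(chemoGenes, panels@macrophageMarkers))
      addGene(g, cfg$chemokineMean * chemoMult)
    stage <- panels@stageGeneCandidates
    stageFac <- matrix(1, nSpot, length(stage),
                       dimnames = list(spotIds, stage))
    if (cfg$stageCoherenceSd > 0) {
      for (j in seq_along(stage)) {
        perTrail <- exp(stats::rnorm(cfg$nTrails, 0, cfg$stageCoherenceSd))
        perSpot <- exp(stats::rnorm(nSpot, 0, cfg$stageCoherenceSd))
        stageFac[, j] <- ifelse(tId > 0 & cfg$coherentStageGenes,
                                perTrail[pmax(tId, 1)], perSpot)
      }
    }
    for (j in seq_along(stage))
      addGene(stage[j], ifelse(isT, cfg$stageMean * dens * stageFac[, j],
                               lowBg))
    vgenes <- c(paste0("TRAV", 1:3), paste0("TRAJ", 1:3), paste0("TRBV", 1:3))
    clone <- lapply(seq_len(cfg$nTrails), function(k)
      sample(vgenes, 3))
    for (g in vgenes) {
      onClone <- tId > 0 & vapply(tId, function(k)
        k > 0 && g %in% clone[[k]], logical(1))
      addGene(g, ifelse(onClone, 2 * dens, ifelse(isT, 0.3 * dens, lowBg)))
    }
    for (j in seq_len(cfg$nBackgroundGenes))
      addGene(sprintf("GENE%04d", j), rep(cfg$baselineMean, nSpot))

    mu <- do.call(rbind, genes)
    rownames(mu) <- names(genes)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = cfg$nbSize),
                     nrow = nrow(mu), dimnames = list(rownames(mu), spotIds))
    if (cfg$dropout > 0) {
      keepMask <- matrix(stats::runif(length(counts)) >= cfg$dropout,
                         nrow = nrow(counts))
      counts <- counts * keepMask
    }
    # guard against pathological empty spots (background makes this rare)
    empty <- colSums(counts) == 0
    if (any(empty)) counts["GENE0001", empty] <- 1
    ds <- STDataset(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                "CsparseMatrix"),
                    cbind(x = grid$x, y = grid$y),
                    platform = "visium", pitch_um = cfg$pitchUm)
    effects <- data.frame(
      gene = rownames(mu),
      class = c(rep("t_marker", length(panels@tMarkers)),
                rep("exhaustion", length(panels@exhaustionMarkers)),
                rep("chemokine", length(chemoGenes)),
                rep("macrophage", length(panels@macrophageMarkers)),
                rep("stage", length(stage)),
                rep("vgene", length(vgenes)),
                rep("background", cfg$nBackgroundGenes)),
      stringsAsFactors = FALSE)
    list(dataset = ds,
         truth = list(trails = trailSpots, tSpots = tSpots,
                      grid = grid, effects = effects, config = cfg))
  })
}

#' Write a simulated slide as a spaceranger-style directory
#'
#' Emits \code{matrix.mtx}, \code{features.tsv}, \code{barcodes.tsv}, a
#' headered \code{tissue_positions.csv} (and the headerless v1
#' \code{tissue_positions_list.csv}), \code{scalefactors_json.json} and the
#' ground truth as sidecar CSVs, readable by \code{\link{readVisium}}.
#'
#' @param ds an \linkS4class{STDataset} from \code{\link{simulateDataset}}.
#' @param truth the matching ground-truth list (or NULL to skip sidecars).
#' @param path output directory (created if needed).
#' @param micronsPerPixel fake full-resolution scale (default 0.5).
#' @return \code{path}, invisibly.
#' @export
writeVisiumLike <- function(ds, truth, path, micronsPerPixel = 0.5) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory: ", path)
  cnt <- assay(ds, "counts")
  Matrix::writeMM(methods::as(cnt, "CsparseMatrix"),
                  file.path(path, "matrix.mtx"))
  utils::write.table(
    data.frame(id = rownames(ds), name = rownames(ds),
               type = "Gene Expression"),
    file.path(path, "features.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  writeLines(colnames(ds), file.path(path, "barcodes.tsv"))
  xy <- spotCoords(ds)
  pitch <- pitchUm(ds)
  arow <- as.integer(round(xy[, "y"] / (pitch * sqrt(3) / 2)))
  acol <- as.integer(round(2 * xy[, "x"] / pitch))
  pos <- data.frame(barcode = colnames(ds), in_tissue = 1L,
                    array_row = arow, array_col = acol,
                    pxl_row_in_fullres = xy[, "y"] / micronsPerPixel,
                    pxl_col_in_fullres = xy[, "x"] / micronsPerPixel)
  utils::write.csv(pos, file.path(path, "tissue_positions.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.table(pos, file.path(path, "tissue_positions_list.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(
    list(microns_per_pixel = micronsPerPixel,
         spot_diameter_fullres = 55 / micronsPerPixel),
    file.path(path, "scalefactors_json.json"), auto_unbox = TRUE)
  if (!is.null(truth)) {
    tt <- do.call(rbind, lapply(seq_along(truth$trails), function(k)
      data.frame(trail_id = k, position = seq_along(truth$trails[[k]]),
                 spot_id = truth$trails[[k]])))
    utils::write.csv(tt, file.path(path, "ground_truth_trails.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(spot_id = truth$tSpots),
                     file.path(path, "ground_truth_tspots.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

#' Simulate trail-indexed expression for trend-test calibration
#'
#' Lightweight generator for the mixed-model trend test: \code{nTrails}
#' straight trails of \code{len} nodes each, with per-node gene-set
#' expression \code{y = mu0 * exp(logFcPerStep * (index - 1)) + b_t + e},
#' where \code{b_t} is a Gaussian random trail intercept and \code{e}
#' Gaussian noise. With \code{logFcPerStep = 0} this is the null model
#' (random intercepts, no index effect); a positive value plants a
#' log-linear gradient of the given per-step fold change.
#'
#' @param nTrails number of trails (default 20).
#' @param len nodes per trail (default 7).
#' @param logFcPerStep log fold change of the mean per index step
#'   (default 0; use log(1.3) for a 1.3x-per-step gradient).
#' @param mu0 baseline mean (default 10).
#' @param interceptSd sd of the random trail intercepts (default 2).
#' @param noiseSd residual sd (default 2).
#' @param seed RNG seed.
#' @return List: \code{trails} (list of \linkS4class{Trail}s), \code{mat}
#'   (1 x node matrix for gene \code{"SETGENE"}), \code{genes}.
#' @export
simulateTrendData <- function(nTrails = 20, len = 7, logFcPerStep = 0,
                              mu0 = 10, interceptSd = 2, noiseSd = 2,
                              seed = 1) {
  withSeed(seed, {
    ids <- as.vector(vapply(seq_len(nTrails), function(t)
      sprintf("t%02d_n%d", t, seq_len(len)), character(len)))
    nodes <- NodeTable(data.frame(
      node_id = ids,
      x = rep(seq_len(len) - 1, nTrails) * 110,
      y = rep(seq_len(nTrails) - 1, each = len) * 500,
      z = rep(seq_len(len) - 1, nTrails),
      t_marker_sum = 1, umi_total = 1000))
    trails <- lapply(seq_len(nTrails), function(t)
      Trail(ids[(t - 1) * len + seq_len(len)], nodes, method = "planted"))
    b <- stats::rnorm(nTrails, 0, interceptSd)
    idx <- rep(seq_len(len) - 1, nTrails)
    y <- mu0 * exp(logFcPerStep * idx) + rep(b, each = len) +
      stats::rnorm(nTrails * len, 0, noiseSd)
    mat <- matrix(y, nrow = 1, dimnames = list("SETGENE", ids))
    list(trails = trails, mat = mat, genes = "SETGENE")
  })
}
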