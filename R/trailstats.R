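#' Mixed-effects trend test along trails
#'
#' Tests whether the summed normalized expression of a gene set increases
#' along the trails: the per-node gene-set sum is the response, the 1-based
#' node index along each trail the fixed covariate, and trails enter as
#' random intercepts. The model is fitted by maximum likelihood
#' (\pkg{lme4}); a positive slope with a two-sided Wald p below 0.05 is
#' read as a significantly increasing trend. If the mixed fit is singular
#' the slope is re-estimated as the mean of per-trail OLS slopes with a
#' one-sample t-test (logged as a fallback).
#'
#' @param trails list of \linkS4class{Trail}s (>= 2, each >= 3 nodes).
#' @param mat gene x node normalized matrix (\code{\link{nodeExpression}}).
#' @param genes gene-set symbols (summed; absent genes are dropped).
#' @param setName label for the output row.
#' @return One-row data.frame: \code{gene_set}, \code{beta}, \code{se},
#'   \code{p}, \code{n_obs}, \code{n_trails}, \code{sd_trail},
#'   \code{sd_resid}, \code{method}.
#' @export
trendTest <- function(trails, mat, genes, setName = "gene_set") {
  if (length(trails) < 2) stop("need at least 2 trails")
  genes <- intersect(genes, rownames(mat))
  if (length(genes) == 0) stop("none of the genes are in the matrix")
  df <- do.call(rbind, lapply(seq_along(trails), function(i) {
    ids <- trailNodes(trails[[i]])
    data.frame(trail = i, index = seq_along(ids),
               y = colSums(mat[genes, ids, drop = FALSE]))
  }))
  if (min(table(df$trail)) < 3) stop("each trail needs >= 3 nodes")
  df$trail <- factor(df$trail)
  fit <- tryCatch(
    suppressMessages(
      lme4::lmer(y ~ index + (1 | trail), data = df, REML = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
    co <- summary(fit)$coefficients
    beta <- co["index", "Estimate"]
    se <- co["index", "Std. Error"]
    p <- 2 * stats::pnorm(-abs(beta / se))
    vc <- as.data.frame(lme4::VarCorr(fit))
    out <- data.frame(gene_set = setName, beta = beta, se = se, p = p,
                      n_obs = nrow(df), n_trails = nlevels(df$trail),
                      sd_trail = vc$sdcor[vc$grp == "trail"],
                      sd_resid = vc$sdcor[vc$grp == "Residual"],
                      method = "lmm_ml")
  } else {
    message("singular mixed fit for '", setName,
            "': falling back to per-trail OLS slopes")
    slopes <- vapply(split(df, df$trail), function(d)
      unname(stats::coef(stats::lm(y ~ index, data = d))[2]), numeric(1))
    if (stats::sd(slopes) < 1e-12) {
      # degenerate: every trail has the same slope (e.g. noise-free data)
      se <- 0
      p <- if (abs(mean(slopes)) > 1e-12) 0 else 1
    } else {
      tt <- stats::t.test(slopes)
      se <- unname(tt$stderr)
      p <- tt$p.value
    }
    out <- data.frame(gene_set = setName, beta = mean(slopes),
                      se = se, p = p,
                      n_obs = nrow(df), n_trails = nlevels(df$trail),
                      sd_trail = NA_real_, sd_resid = NA_real_,
                      method = "ols_fallback")
  }
  rownames(out) <- NULL
  out
}

# unique spots covered by a list of node-id sequences
.coveredNodes <- function(seqs) unique(unlist(seqs, use.names = FALSE))

#' Empirical differential expression on trails vs matched controls
#'
#' Per gene, the observed statistic is the mean normalized expression over
#' all on-trail nodes; the null distribution is the same statistic computed
#' on each matched control set. Two-sided empirical p-values are adjusted
#' by Benjamini-Hochberg; the fold change is the observed mean over the
#' mean of the per-set null means. A gene is called up when adjusted
#' p < \code{fdrCut} and FC > \code{fcCut} (down for FC < 1/\code{fcCut}).
#'
#' @param trails list of final \linkS4class{Trail}s.
#' @param controlSets control sets (\code{\link{generateControlSets}}).
#' @param mat gene x node normalized matrix.
#' @param genes genes to test (typically the variable genes).
#' @param fcCut fold-change threshold (default 1.2).
#' @param fdrCut FDR threshold (default 0.05).
#' @param convention empirical p convention (\code{\link{empiricalP}}).
#' @return data.frame with one row per gene: \code{gene}, \code{obs_mean},
#'   \code{null_mean}, \code{fc}, \code{p}, \code{p_adj}, \code{call}.
#' @export
deTest <- function(trails, controlSets, mat, genes, fcCut = 1.2,
                   fdrCut = 0.05, convention = "plain") {
  missing <- setdiff(genes, rownames(mat))
  if (length(missing))
    warning(length(missing), " gene(s) absent from the matrix; skipped")
  genes <- intersect(genes, rownames(mat))
  onTrail <- .coveredNodes(lapply(trails, trailNodes))
  obs <- rowMeans(mat[genes, onTrail, drop = FALSE])
  nullMat <- vapply(controlSets, function(set)
    rowMeans(mat[genes, .coveredNodes(set), drop = FALSE]),
    numeric(length(genes)))
  if (length(genes) == 1)
    nullMat <- matrix(nullMat, nrow = 1, dimnames = list(genes, NULL))
  n <- ncol(nullMat)
  ge <- rowSums(nullMat >= obs)
  le <- rowSums(nullMat <= obs)
  p <- if (convention == "plain") pmin(1, 2 * pmin(ge, le) / n)
       else pmin(1, 2 * (pmin(ge, le) + 1) / (n + 1))
  nullMean <- rowMeans(nullMat)
  fc <- obs / nullMean
  padj <- stats::p.adjust(p, method = "BH")
  call <- ifelse(padj < fdrCut & fc > fcCut, "up",
                 ifelse(padj < fdrCut & fc < 1 / fcCut, "down", "ns"))
  data.frame(gene = genes, obs_mean = unname(obs),
             null_mean = unname(nullMean), fc = unname(fc),
             p = unname(p), p_adj = unname(padj), call = call,
             row.names = NULL)
}

#' Shared TCR/BCR variable genes along trails
#'
#' A variable gene is "shared" by a consecutive node pair when its raw
#' count is positive in both nodes (detection, not magnitude). Per trail
#' the shared counts of consecutive pairs are averaged; the observed
#' statistic is the median of these trail means, compared against the same
#' statistic on each matched control set by a two-sided empirical p-value.
#' TCR surrogates are the TRAV/TRAJ/TRBV genes; the same machinery applies
#' to BCR variable genes via the \code{bcr} pattern.
#'
#' @param trails list of final \linkS4class{Trail}s.
#' @param controlSets control sets (\code{\link{generateControlSets}}).
#' @param counts gene x node raw count matrix.
#' @param pattern regex matching variable-gene symbols (e.g.
#'   \code{defaultGenePanels()@vgenePatterns$tcr}).
#' @param convention empirical p convention.
#' @return List: \code{observed} (median over trails), \code{perTrail},
#'   \code{null} (one median per control set), \code{p}, \code{n_vgenes}.
#' @export
sharedVgeneTest <- function(trails, controlSets, counts, pattern,
                            convention = "plain") {
  vg <- grep(pattern, rownames(counts), value = TRUE)
  if (length(vg) == 0) {
    pref <- sort(unique(sub("^([A-Z0-9]{3,4}).*", "\\1", rownames(counts))))
    stop("no genes match '", pattern, "'; available prefixes include: ",
         paste(utils::head(pref, 20), collapse = ", "))
  }
  det <- as.matrix(counts[vg, , drop = FALSE]) > 0
  seqMean <- function(ids) {
    n <- length(ids)
    if (n < 2) return(NA_real_)
    mean(vapply(seq_len(n - 1), function(k)
      sum(det[, ids[k]] & det[, ids[k + 1]]), numeric(1)))
  }
  perTrail <- vapply(trails, function(tr) seqMean(trailNodes(tr)), numeric(1))
  observed <- stats::median(perTrail)
  nullVals <- vapply(controlSets, function(set)
    stats::median(vapply(set, seqMean, numeric(1))), numeric(1))
  list(observed = observed, perTrail = perTrail, null = nullVals,
       p = empiricalP(observed, nullVals, convention = convention),
       n_vgenes = length(vg))
}

#' Over-representation analysis by Fisher's exact test
#'
#' One-sided (enrichment) Fisher exact test of a query gene list against
#' each gene set, on the 2x2 table in-query x in-set over the universe;
#' the p-value is the hypergeometric upper tail. P-values are BH-adjusted
#' across sets and the table is sorted by adjusted p.
#'
#' @param query gene list (must lie within the universe).
#' @param sets a \linkS4class{GeneSetList}.
#' @param universe background gene list; defaults to the collection's
#'   universe.
#' @return data.frame: \code{set}, \code{overlap}, \code{set_size},
#'   \code{query_size}, \code{p}, \code{p_adj}.
#' @export
oraFisher <- function(query, sets, universe = NULL) {
  if (is.null(universe)) universe <- sets@universe
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  if (!all(query %in% universe))
    stop("query genes must be a subset of the universe")
  query <- unique(query)
  N <- length(universe)
  k <- length(query)
  res <- lapply(names(geneSets(sets)), function(nm) {
    s <- intersect(geneSets(sets)[[nm]], universe)
    a <- length(intersect(query, s))
    m <- length(s)
    p <- stats::phyper(a - 1, m, N - m, k, lower.tail = FALSE)
    data.frame(set = nm, overlap = a, set_size = m, query_size = k, p = p)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p_adj, out$p, out$set), , drop = FALSE]
}

#' Rank trail-upregulated genes across single-cell clusters
#'
#' For each upregulated gene, the per-cluster mean expressions are ranked
#' ascending (ties share the average rank; with 13 clusters, rank 13 marks
#' the cluster with the largest mean). Clusters accumulating high ranks
#' across genes are enriched for the migrating-T-cell signature; the
#' summary orders clusters by median rank, descending.
#'
#' @param upGenes genes upregulated on trails.
#' @param clusterMeans cluster x gene matrix of per-cluster mean expression
#'   (e.g. from an annotated single-cell reference).
#' @return List: \code{ranks} (cluster x gene rank matrix) and
#'   \code{summary} (data.frame \code{cluster}, \code{median_rank},
#'   \code{mean_rank}, ordered by median rank descending).
#' @export
phenotypeRank <- function(upGenes, clusterMeans) {
  if (nrow(clusterMeans) < 2) stop("need at least 2 clusters")
  genes <- intersect(upGenes, colnames(clusterMeans))
  if (length(genes) == 0)
    stop("no overlap between upGenes and the cluster-mean table")
  ranks <- apply(clusterMeans[, genes, drop = FALSE], 2, rank,
                 ties.method = "average")
  med <- apply(ranks, 1, stats::median)
  mn <- rowMeans(ranks)
  ord <- order(-med, -mn)
  list(ranks = ranks,
       summary = data.frame(cluster = rownames(clusterMeans)[ord],
                            median_rank = med[ord], mean_rank = mn[ord],
                            row.names = NULL))
}
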