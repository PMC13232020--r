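#' Read a spaceranger-style Visium directory
#'
#' Expects the usual trio \code{matrix.mtx} (genes x barcodes),
#' \code{features.tsv}, \code{barcodes.tsv}, plus a tissue-positions table
#' (\code{tissue_positions.csv} headered v2 dialect, or
#' \code{tissue_positions_list.csv} headerless v1 dialect) and, optionally,
#' \code{scalefactors_json.json}. Only in-tissue spots are kept.
#'
#' Micron coordinates are taken from the full-resolution pixel coordinates
#' scaled by \code{microns_per_pixel} when the scale-factor file provides it
#' (directly, or derived from \code{spot_diameter_fullres} assuming a 55 um
#' spot); otherwise from the array (row, col) coordinates on the standard
#' interleaved hexagonal layout: x = col * pitch/2, y = row * pitch * sqrt(3)/2.
#'
#' @param path directory containing the files above.
#' @param platform \code{"visium"} (default) or \code{"visium_hd"}.
#' @param pitch_um spot pitch in microns used for the array-coordinate
#'   fallback (default 110).
#' @return An \linkS4class{STDataset} of in-tissue spots.
#' @seealso \code{\link{writeVisiumLike}} for the emitting side.
#' @export
readVisium <- function(path, platform = c("visium", "visium_hd"),
                       pitch_um = 110) {
  platform <- match.arg(platform)
  f <- function(name) {
    p <- file.path(path, name)
    if (!file.exists(p)) stop("missing file: ", p)
    p
  }
  mat <- Matrix::readMM(f("matrix.mtx"))
  feats <- utils::read.delim(f("features.tsv"), header = FALSE,
                             stringsAsFactors = FALSE)
  bcs <- utils::read.delim(f("barcodes.tsv"), header = FALSE,
                           stringsAsFactors = FALSE)[, 1]
  if (nrow(mat) != nrow(feats))
    stop("format error: matrix has ", nrow(mat), " rows but features.tsv has ",
         nrow(feats))
  if (ncol(mat) != length(bcs))
    stop("format error: matrix has ", ncol(mat),
         " columns but barcodes.tsv has ", length(bcs))
  geneNames <- if (ncol(feats) >= 2) feats[, 2] else feats[, 1]
  geneNames <- make.unique(as.character(geneNames))
  dimnames(mat) <- list(geneNames, bcs)

  pos <- .readTissuePositions(path)
  pos <- pos[pos$in_tissue == 1, , drop = FALSE]
  pos <- pos[pos$barcode %in% bcs, , drop = FALSE]
  if (nrow(pos) == 0) stop("no in-tissue spots found")

  sf <- .readScaleFactors(path)
  if (!is.null(sf$microns_per_pixel)) {
    x <- pos$pxl_col_in_fullres * sf$microns_per_pixel
    y <- pos$pxl_row_in_fullres * sf$microns_per_pixel
  } else {
    x <- pos$array_col * pitch_um / 2
    y <- pos$array_row * pitch_um * sqrt(3) / 2
  }
  mat <- mat[, match(pos$barcode, bcs), drop = FALSE]
  STDataset(methods::as(mat, "CsparseMatrix"), cbind(x = x, y = y),
            platform = platform, pitch_um = pitch_um)
}

.readTissuePositions <- function(path) {
  v2 <- file.path(path, "tissue_positions.csv")
  v1 <- file.path(path, "tissue_positions_list.csv")
  cols <- c("barcode", "in_tissue", "array_row", "array_col",
            "pxl_row_in_fullres", "pxl_col_in_fullres")
  if (file.exists(v2)) {
    pos <- utils::read.csv(v2, stringsAsFactors = FALSE)
    if (!all(cols %in% colnames(pos)))
      stop("format error: tissue_positions.csv lacks standard columns")
    pos[, cols]
  } else if (file.exists(v1)) {
    pos <- utils::read.csv(v1, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(pos) != 6)
      stop("format error: tissue_positions_list.csv must have 6 columns")
    stats::setNames(pos, cols)
  } else stop("missing file: ", v2, " (or tissue_positions_list.csv)")
}

.readScaleFactors <- function(path) {
  p <- file.path(path, "scalefactors_json.json")
  if (!file.exists(p)) return(list())
  sf <- jsonlite::read_json(p, simplifyVector = TRUE)
  if (is.null(sf$microns_per_pixel) && !is.null(sf$spot_diameter_fullres))
    sf$microns_per_pixel <- 55 / sf$spot_diameter_fullres
  sf
}

#' TPM-like per-spot normalization
#'
#' Scales each spot's counts to sum to 1e6 (transcripts-per-million style
#' depth normalization) and stores the result as the \code{"tpm"} assay.
#' Spots with zero total UMIs are dropped with a warning.
#'
#' @param ds an \linkS4class{STDataset}.
#' @return The dataset with a \code{"tpm"} assay added.
#' @examples
#' cnt <- matrix(c(2, 3, 5), nrow = 3,
#'               dimnames = list(c("A", "B", "C"), "S1"))
#' ds <- normalizeCounts(STDataset(cnt, cbind(0, 0)))
#' tpmMatrix(ds)[, 1]  # 2e5 3e5 5e5
#' @export
normalizeCounts <- function(ds) {
  tot <- umiTotals(ds)
  if (all(tot == 0)) stop("all spots have zero total counts")
  if (any(tot == 0)) {
    warning(sum(tot == 0), " zero-UMI spot(s) dropped")
    ds <- ds[, tot > 0]
    tot <- tot[tot > 0]
  }
  cnt <- assay(ds, "counts")
  tpm <- t(t(as.matrix(cnt)) / tot) * 1e6
  SummarizedExperiment::assay(ds, "tpm", withDimnames = FALSE) <- tpm
  ds
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of their log1p-transformed normalized
#' expression and returns the top \code{n}. Deterministic: ties are broken
#' by the original gene order.
#'
#' @param mat gene x spot normalized matrix (e.g. \code{tpmMatrix(ds)}).
#' @param n number of genes to keep (default 3000, capped at nrow).
#' @return Character vector of gene names.
#' @export
selectVariableGenes <- function(mat, n = 3000) {
  if (n <= 0) stop("n must be positive")
  if (n > nrow(mat)) stop("n exceeds the number of genes")
  lg <- log1p(as.matrix(mat))
  v <- apply(lg, 1, stats::var)
  rownames(mat)[order(-v)[seq_len(n)]]
}

#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, then member genes. Duplicate
#' genes within a set are kept once.
#'
#' @param path GMT file path.
#' @param universe optional background gene list attached to the collection.
#' @return A \linkS4class{GeneSetList}.
#' @examples
#' gmt <- system.file("extdata", "synthetic_gene_sets.gmt",
#'                    package = "TcellTrails")
#' readGmt(gmt)
#' @export
readGmt <- function(path, universe = character(0)) {
  if (!file.exists(path)) stop("missing file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("format error at line ", i, ": expected >= 3 tab-separated fields")
    sets[[fields[1]]] <- unique(fields[-(1:2)])
  }
  GeneSetList(sets, universe = universe)
}

#' Write a GeneSetList as GMT
#'
#' @param x a \linkS4class{GeneSetList}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGmt <- function(x, path) {
  lines <- vapply(names(geneSets(x)), function(nm)
    paste(c(nm, "na", geneSets(x)[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}
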