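#' Counts-per-million normalization with log10 pseudocount
#'
#' Adds a \code{cpm} assay (each cell's counts scaled to one million) and a
#' \code{logcpm} assay, \eqn{\log_{10}(\mathrm{cpm} + 0.1)}, so a zero
#' count maps to exactly \eqn{-1}. An all-zero cell passes through as
#' zeros with a warning (its \code{logcpm} is \eqn{-1} everywhere).
#'
#' @param sce a \code{SingleCellExperiment} with a \code{counts} assay.
#' @param pseudocount pseudocount on the CPM scale (default 0.1).
#' @return the experiment with \code{cpm} and \code{logcpm} assays.
#' @export
cpmNormalize <- function(sce, pseudocount = 0.1) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  libSizes <- Matrix::colSums(counts)
  empty <- libSizes == 0
  if (any(empty))
    atlasWarn("cpm_normalize", sum(empty),
              " all-zero cells pass through as zeros")
  div <- ifelse(empty, 1, libSizes)
  cpm <- Matrix::t(Matrix::t(counts) / div) * 1e6
  SummarizedExperiment::assay(sce, "cpm") <- cpm
  SummarizedExperiment::assay(sce, "logcpm") <-
    log10(as.matrix(cpm) + pseudocount)
  S4Vectors::metadata(sce)$cpm_pseudocount <- pseudocount
  sce
}

# Per-gene Fano factor (variance / mean) over a set of cells, on the CPM
# scale; genes with zero mean get NA.
fanoFactor <- function(cpm) {
  m <- Matrix::rowMeans(cpm)
  sq <- Matrix::rowMeans(cpm^2)
  v <- pmax(0, (sq - m^2)) * ncol(cpm) / max(1, ncol(cpm) - 1)
  f <- v / m
  f[m == 0] <- NA_real_
  f
}

#' Select features with a high Fano factor in most mice
#'
#' For every mouse with at least \code{minCellsPerMouse} cells, computes
#' the per-gene Fano factor (variance/mean) of CPM over that mouse's cells
#' and ranks genes by decreasing Fano (genes with zero mean in a mouse get
#' the worst rank). A gene's support is the number of mice in which its
#' rank is within \code{highRankCutoff}. The \code{nFeatures} genes are
#' selected by decreasing support, then increasing mean rank, then gene
#' symbol. Genes expressed in no usable mouse are ineligible; when fewer
#' than \code{nFeatures} genes are eligible all of them are returned with
#' a warning.
#'
#' @param sce a \code{SingleCellExperiment} with a \code{cpm} assay
#'   (see \code{\link{cpmNormalize}}) and \code{mouse_id} in
#'   \code{colData}.
#' @param nFeatures number of genes to select (default 500).
#' @param highRankCutoff within-mouse rank below which a gene counts as
#'   high-Fano (default 1000).
#' @param minCellsPerMouse mice with fewer cells are skipped with a
#'   warning (default 5).
#' @param excludeGenes genes to exclude from selection regardless of
#'   their Fano factor (e.g. cell-cycle genes before a trajectory
#'   analysis, where the proliferation axis would otherwise dominate the
#'   geometry); default none.
#' @return a \linkS4class{FanoFeatures} object.
#' @export
fanoFeatureSelect <- function(sce, nFeatures = 500L,
                              highRankCutoff = 1000L,
                              minCellsPerMouse = 5L,
                              excludeGenes = character(0)) {
  if (!"cpm" %in% SummarizedExperiment::assayNames(sce))
    atlasStop("fano_select", "run cpmNormalize first (no cpm assay)")
  mice <- as.character(sce$mouse_id)
  sizes <- table(mice)
  usable <- names(sizes)[sizes >= minCellsPerMouse]
  if (length(usable) < length(sizes))
    atlasWarn("fano_select", "skipping mice with < ", minCellsPerMouse,
              " cells: ",
              paste(setdiff(names(sizes), usable), collapse = ", "))
  if (length(usable) < 2)
    atlasStop("fano_select", "need at least 2 usable mice")
  cpm <- SummarizedExperiment::assay(sce, "cpm")
  nG <- nrow(sce)
  ranks <- matrix(NA_real_, nG, length(usable),
                  dimnames = list(rownames(sce), usable))
  for (m in usable) {
    f <- fanoFactor(cpm[, mice == m, drop = FALSE])
    r <- rank(-f, ties.method = "first", na.last = "keep")
    r[is.na(r)] <- nG  # zero-mean genes: worst rank
    ranks[, m] <- r
  }
  support <- as.integer(rowSums(ranks <= highRankCutoff))
  names(support) <- rownames(sce)
  eligible <- Matrix::rowSums(cpm[, mice %in% usable, drop = FALSE]) > 0
  eligible[rownames(sce) %in% excludeGenes] <- FALSE
  nSel <- min(nFeatures, sum(eligible))
  if (nSel < nFeatures)
    atlasWarn("fano_select", "only ", sum(eligible),
              " eligible genes; returning all of them")
  meanRank <- rowMeans(ranks)
  ord <- order(-support, meanRank, rownames(sce))
  ord <- ord[eligible[ord]]
  methods::new("FanoFeatures",
    selectedGenes = rownames(sce)[ord[seq_len(nSel)]],
    support = support,
    rankTable = ranks,
    params = list(n_features = nFeatures,
                  high_rank_cutoff = highRankCutoff,
                  mice = usable))
}

#' Project cells onto principal components of the selected features
#'
#' PCA of the log-transformed CPM matrix (pseudocount 0.1) restricted to
#' the selected genes. Genes are centered but not unit-scaled; a
#' deterministic eigensolver and sign convention (the largest-magnitude
#' loading of each component is positive) make the projection fully
#' reproducible. The cell coordinates are stored as the \code{"PCA"}
#' reduced dimension with the loadings and per-component variances as
#' attributes.
#'
#' @param sce a \code{SingleCellExperiment} with a \code{logcpm} assay.
#' @param features a \linkS4class{FanoFeatures} object (or a character
#'   vector of gene symbols).
#' @param k number of components (default 25).
#' @return the experiment with \code{reducedDim(., "PCA")} set; the matrix
#'   carries attributes \code{"loadings"} (gene x component) and
#'   \code{"explainedVariance"}.
#' @export
pcaProject <- function(sce, features, k = 25L) {
  genes <- if (methods::is(features, "FanoFeatures"))
    selectedGenes(features) else as.character(features)
  genes <- intersect(genes, rownames(sce))
  if (k > length(genes))
    atlasStop("pca_project", "k = ", k, " exceeds the ", length(genes),
              " selected features")
  x <- t(as.matrix(SummarizedExperiment::assay(sce, "logcpm")[genes, ,
                                                              drop = FALSE]))
  fit <- prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
  coords <- fit$x[, seq_len(k), drop = FALSE]
  load <- fit$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {  # sign convention: top-|loading| positive
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      coords[, j] <- -coords[, j]
    }
  }
  attr(coords, "loadings") <- load
  attr(coords, "explainedVariance") <- fit$sdev[seq_len(k)]^2
  attr(coords, "totalVariance") <- sum(fit$sdev^2)
  attr(coords, "genes") <- genes
  SingleCellExperiment::reducedDim(sce, "PCA") <- coords
  sce
}
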