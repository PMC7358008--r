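#' Smooth per-cell values over a kNN graph
#'
#' One smoothing round replaces each cell's value by the mean over the
#' cell and its graph neighbors (row-normalized adjacency with self-loop);
#' \code{rounds} rounds reach exactly \code{rounds}-order neighbors.
#' Constant vectors are fixed points, isolated cells are unchanged, and
#' per-feature variance is non-increasing every round.
#'
#' @param x numeric matrix with one row per cell (columns are genes or
#'   any per-cell features), or a vector with one value per cell.
#' @param g an \pkg{igraph} graph over the same cells, in row order.
#' @param rounds smoothing rounds (default 2, reaching second-order
#'   neighbors).
#' @return the smoothed matrix (or vector), same shape as the input.
#' @export
smoothOverGraph <- function(x, g, rounds = 2L) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (igraph::vcount(g) != n)
    atlasStop("smoothing", "graph has ", igraph::vcount(g),
              " vertices but matrix has ", n, " cells")
  if (rounds < 1) atlasStop("smoothing", "rounds must be >= 1")
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  A <- ((A > 0) * 1) + Matrix::Diagonal(n)    # binary adjacency + self-loop
  deg <- Matrix::rowSums(A)
  # sum over the neighborhood first, divide once: keeps constant vectors
  # exact fixed points
  for (r in seq_len(rounds)) x <- as.matrix(A %*% x) / deg
  if (vec) x[, 1] else x
}

#' Second-order kNN-graph smoothing of the normalized matrix
#'
#' Applies \code{\link{smoothOverGraph}} to the CPM matrix over the same
#' symmetrized kNN graph used for clustering and embedding, storing the
#' result as assays \code{smooth_cpm} and \code{smooth_logcpm} (log10 with
#' the 0.1 pseudocount). Two rounds reach second-order neighbors. The
#' smoothed values are intended for visualizing low or noisy genes only;
#' clustering and differential expression always use unsmoothed values.
#'
#' @param sce a \code{SingleCellExperiment} with a \code{cpm} assay.
#' @param g the kNN graph over the same cells
#'   (see \code{\link{buildKnnGraph}}).
#' @param rounds smoothing rounds (default 2).
#' @return the experiment with \code{smooth_cpm} and \code{smooth_logcpm}
#'   assays and \code{metadata(.)$smoothing_rounds} set.
#' @export
smoothExpression <- function(sce, g, rounds = 2L) {
  if (!"cpm" %in% SummarizedExperiment::assayNames(sce))
    atlasStop("smoothing", "run cpmNormalize first (no cpm assay)")
  if (igraph::vcount(g) != ncol(sce))
    atlasStop("smoothing", "graph and experiment disagree on cells")
  cpmMat <- as.matrix(SummarizedExperiment::assay(sce, "cpm"))
  sm <- t(smoothOverGraph(t(cpmMat), g, rounds = rounds))
  dimnames(sm) <- dimnames(cpmMat)
  pseudo <- S4Vectors::metadata(sce)$cpm_pseudocount
  if (is.null(pseudo)) pseudo <- 0.1
  SummarizedExperiment::assay(sce, "smooth_cpm") <- sm
  SummarizedExperiment::assay(sce, "smooth_logcpm") <- log10(sm + pseudo)
  S4Vectors::metadata(sce)$smoothing_rounds <- rounds
  sce
}
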