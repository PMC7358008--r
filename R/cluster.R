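#' Build a symmetrized k-nearest-neighbor graph in PC space
#'
#' Euclidean kNN over the PCA coordinates, symmetrized by edge union
#' (an edge exists when either endpoint lists the other among its k
#' nearest neighbors), unweighted. Distance ties are broken by ascending
#' cell index, making the graph fully deterministic.
#'
#' @param sce a \code{SingleCellExperiment} with a \code{"PCA"} reduced
#'   dimension (see \code{\link{pcaProject}}), or a numeric coordinate
#'   matrix with one row per cell.
#' @param k neighbors per cell (default 15); must be smaller than the
#'   number of cells.
#' @return an undirected \pkg{igraph} graph whose vertex names are the
#'   cell identifiers.
#' @export
buildKnnGraph <- function(sce, k = 15L) {
  coords <- if (is.matrix(sce)) sce else
    SingleCellExperiment::reducedDim(sce, "PCA")
  n <- nrow(coords)
  if (k >= n)
    atlasStop("build_knn", "k = ", k, " must be below the ", n, " cells")
  nn <- knnIndices(coords, k)
  a <- rep(seq_len(n), each = k)
  b <- as.vector(t(nn))
  edges <- unique(cbind(pmin(a, b), pmax(a, b)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  ids <- if (!is.null(rownames(coords))) rownames(coords)
         else as.character(seq_len(n))
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::V(g)$name <- ids
  g
}

#' Leiden community detection
#'
#' Runs Leiden modularity optimization on the kNN graph at the given
#' resolution. Communities are relabeled as contiguous integers from 0 in
#' order of decreasing size, so the same graph and seed always give
#' identical labels.
#'
#' @param g an undirected \pkg{igraph} graph.
#' @param resolution resolution parameter of the modularity objective
#'   (default 1).
#' @param seed integer seed (default 0).
#' @param nIterations Leiden refinement iterations (default 10).
#' @return an integer vector of community labels (0-based), named by the
#'   vertex names.
#' @export
leidenCluster <- function(g, resolution = 1, seed = 0L,
                          nIterations = 10L) {
  if (igraph::vcount(g) == 0)
    atlasStop("leiden", "empty graph")
  memb <- withSeed(seed, {
    igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity",
      resolution = resolution, n_iterations = nIterations))
  })
  sizes <- table(memb)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- setNames(seq_along(ord) - 1L, names(sizes)[ord])
  labels <- unname(relabel[as.character(memb)])
  names(labels) <- igraph::V(g)$name
  labels
}

#' t-SNE embedding of the PC coordinates
#'
#' Two-dimensional t-distributed stochastic neighbor embedding of the PCA
#' coordinates, initialized from the first two (scaled) principal
#' components rather than at random so the geometry is stable across runs;
#' with the seed this makes the embedding fully reproducible.
#'
#' @param sce a \code{SingleCellExperiment} with a \code{"PCA"} reduced
#'   dimension, or a coordinate matrix.
#' @param perplexity t-SNE perplexity (default 30); must satisfy
#'   \code{perplexity < (n_cells - 1) / 3}.
#' @param seed integer seed (default 0).
#' @param maxIter gradient-descent iterations (default 1000).
#' @return if given an experiment, the experiment with
#'   \code{reducedDim(., "TSNE")} set; otherwise the n x 2 coordinate
#'   matrix.
#' @export
tsneEmbed <- function(sce, perplexity = 30, seed = 0L, maxIter = 1000L) {
  coords <- if (is.matrix(sce)) sce else
    SingleCellExperiment::reducedDim(sce, "PCA")
  n <- nrow(coords)
  if (perplexity >= (n - 1) / 3)
    atlasStop("tsne", "perplexity ", perplexity,
              " too large for ", n, " cells (need < (n-1)/3)")
  init <- coords[, 1:2, drop = FALSE]
  init <- init / stats::sd(init[, 1]) * 1e-4
  emb <- withSeed(seed, {
    Rtsne::Rtsne(coords, dims = 2, perplexity = perplexity,
                 pca = FALSE, Y_init = init, max_iter = maxIter,
                 check_duplicates = FALSE)$Y
  })
  rownames(emb) <- rownames(coords)
  colnames(emb) <- c("tsne1", "tsne2")
  if (is.matrix(sce)) return(emb)
  SingleCellExperiment::reducedDim(sce, "TSNE") <- emb
  sce
}

#' Default marker panel for perinatal lung immune populations
#'
#' The positive marker rules used to name Leiden clusters: \code{Gal}
#' (Mac I), \code{Itgax} (Mac II), \code{Car4} and \code{Itgax} (Mac III),
#' \code{C1qa} (Mac IV), \code{Plac8} (Mac V), \code{Itgae} (cDC1),
#' \code{Cd209a} (cDC2), \code{Mreg} (mig-DC), \code{Mcpt4} (mast),
#' \code{Mcpt8} (basophil), \code{Retnlg} (neutrophil), \code{Ms4a1} (B),
#' \code{Cd3e} (T), \code{Gzma} (NK), \code{Areg} (ILC2).
#'
#' @return a named list; each element is a named numeric vector of genes
#'   with direction +1 (expressed) or -1 (absent).
#' @export
defaultMarkerPanel <- function() {
  list(
    "Mac I" = c(Gal = 1), "Mac II" = c(Itgax = 1),
    "Mac III" = c(Car4 = 1, Itgax = 1), "Mac IV" = c(C1qa = 1),
    "Mac V" = c(Plac8 = 1), "cDC1" = c(Itgae = 1),
    "cDC2" = c(Cd209a = 1), "mig-DC" = c(Mreg = 1),
    "Mast" = c(Mcpt4 = 1), "Basophil" = c(Mcpt8 = 1),
    "Neutrophil" = c(Retnlg = 1), "B" = c(Ms4a1 = 1),
    "T" = c(Cd3e = 1), "NK" = c(Gzma = 1), "ILC2" = c(Areg = 1))
}

#' Annotate clusters with a marker panel
#'
#' Scores every (cluster, cell type) pair as the mean over the type's rule
#' genes of the cluster's expressing fraction (raw count > 0), signed by
#' the rule direction (negative rules contribute
#' \code{-frac_expressing}). Each cluster receives the best-scoring type;
#' clusters whose best score falls below \code{floor} stay
#' \code{"unassigned"}; exact ties go to the type listed first in the
#' panel, with a warning.
#'
#' @param sce a \code{SingleCellExperiment} with \code{counts}.
#' @param labels per-cell cluster labels.
#' @param panel a marker panel as from \code{\link{defaultMarkerPanel}};
#'   genes absent from the matrix are dropped with a warning.
#' @param floor minimum winning score (default 0.25).
#' @return a named character vector mapping cluster label to type name.
#' @export
annotateClusters <- function(sce, labels, panel = defaultMarkerPanel(),
                             floor = 0.25) {
  counts <- SummarizedExperiment::assay(sce, "counts")
  panel <- lapply(panel, function(rule) {
    keep <- names(rule) %in% rownames(sce)
    if (any(!keep))
      atlasWarn("annotate", "panel genes not in matrix dropped: ",
                paste(names(rule)[!keep], collapse = ", "))
    rule[keep]
  })
  panel <- panel[vapply(panel, length, 1L) > 0]
  if (!length(panel))
    atlasStop("annotate", "no panel gene resolves against the matrix")
  labs <- as.character(labels)
  out <- vapply(sort(unique(labs)), function(cl) {
    idx <- which(labs == cl)
    scores <- vapply(panel, function(rule) {
      frac <- Matrix::rowSums(
        counts[names(rule), idx, drop = FALSE] > 0) / length(idx)
      mean(sign(rule) * frac)
    }, numeric(1))
    best <- max(scores)
    if (best < floor) return("unassigned")
    winners <- which(scores == best)
    if (length(winners) > 1)
      atlasWarn("annotate", "cluster ", cl, ": tie between ",
                paste(names(panel)[winners], collapse = ", "),
                "; first in panel order wins")
    names(panel)[winners[1]]
  }, character(1))
  out
}

#' Dot-plot summary of a gene panel across clusters
#'
#' For every (gene, cluster) pair, the fraction of the cluster's cells
#' expressing the gene (raw count > 0, the dot size of a dot plot) and the
#' mean log10 CPM expression (the dot color). The full gene x cluster grid
#' is always returned.
#'
#' @param sce a \code{SingleCellExperiment} with \code{counts} and
#'   \code{logcpm} assays.
#' @param labels per-cell cluster labels.
#' @param genes gene symbols to summarize (must resolve).
#' @return a data.frame with columns \code{gene}, \code{cluster},
#'   \code{frac_expressing}, \code{mean_log_expression}.
#' @export
dotplotSummary <- function(sce, labels, genes) {
  missing <- setdiff(genes, rownames(sce))
  if (length(missing))
    atlasStop("dotplot", "genes not in matrix: ",
              paste(missing, collapse = ", "))
  counts <- SummarizedExperiment::assay(sce, "counts")
  logcpm <- SummarizedExperiment::assay(sce, "logcpm")
  labs <- as.character(labels)
  clusters <- sort(unique(labs))
  grid <- expand.grid(gene = genes, cluster = clusters,
                      stringsAsFactors = FALSE)
  grid$frac_expressing <- NA_real_
  grid$mean_log_expression <- NA_real_
  for (cl in clusters) {
    idx <- which(labs == cl)
    sel <- grid$cluster == cl
    grid$frac_expressing[sel] <- Matrix::rowSums(
      counts[genes, idx, drop = FALSE] > 0) / length(idx)
    grid$mean_log_expression[sel] <-
      rowMeans(logcpm[genes, idx, drop = FALSE])
  }
  grid
}
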