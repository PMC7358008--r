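#' Run the full atlas pipeline on a count experiment
#'
#' The standard analysis chain: read/gene QC filters; CPM normalization;
#' per-mouse Fano feature selection; PCA; kNN graph; a provisional Leiden
#' clustering used to flag and remove doublet clusters (joint expression
#' of the pan-immune marker with mutually exclusive non-immune lineage
#' markers); then re-normalization, re-selection and re-clustering of the
#' cleaned matrix; and finally marker-panel annotation of the clusters.
#'
#' @param sce a \code{SingleCellExperiment} with \code{counts} and
#'   \code{mouse_id}/\code{mapped_reads} metadata.
#' @param minReads,minGenes QC thresholds (defaults 50000 and 400).
#' @param nFeatures Fano-selected features (default 500).
#' @param k number of principal components (default 25).
#' @param knnK neighbors for the kNN graph (default 15).
#' @param resolution Leiden resolution (default 0.4, calibrated once on
#'   the default synthetic design to recover the planted population
#'   count).
#' @param seed integer seed driving Leiden (default 0).
#' @param contaminantMarkers,immuneMarker,fracThreshold doublet-cluster
#'   rule parameters (see \code{\link{flagDoubletClusters}}).
#' @param panel marker panel for annotation
#'   (default \code{\link{defaultMarkerPanel}}); \code{NULL} skips
#'   annotation.
#' @param embed compute the t-SNE embedding (default FALSE; it is not
#'   needed for clustering and dominates runtime).
#' @param perplexity t-SNE perplexity when \code{embed = TRUE}.
#' @return the processed \code{SingleCellExperiment}: cleaned cells,
#'   assays \code{cpm}/\code{logcpm}, reduced dimensions \code{PCA} (and
#'   \code{TSNE} if requested), \code{colData} columns \code{cluster} and
#'   \code{cell_type}, \code{metadata} entries \code{qc_report},
#'   \code{features}, \code{knn_graph}, \code{doublet_clusters} and
#'   \code{cluster_annotation}.
#' @export
runAtlasPipeline <- function(sce, minReads = 50000L, minGenes = 400L,
                             nFeatures = 500L, k = 25L, knnK = 15L,
                             resolution = 0.4, seed = 0L,
                             contaminantMarkers = c("Epcam", "Cdh5",
                                                    "Col6a2"),
                             immuneMarker = "Ptprc",
                             fracThreshold = 0.5,
                             panel = defaultMarkerPanel(),
                             embed = FALSE, perplexity = 30) {
  sce <- filterCells(sce, minReads = minReads, minGenes = minGenes)
  stage <- function(x) {
    x <- cpmNormalize(x)
    feats <- fanoFeatureSelect(x, nFeatures = nFeatures)
    x <- pcaProject(x, feats, k = min(k, length(selectedGenes(feats))))
    g <- buildKnnGraph(x, k = knnK)
    labels <- leidenCluster(g, resolution = resolution, seed = seed)
    S4Vectors::metadata(x)$features <- feats
    S4Vectors::metadata(x)$knn_graph <- g
    x$cluster <- unname(labels)
    x
  }
  sce <- stage(sce)
  flagged <- flagDoubletClusters(sce, sce$cluster,
                                 contaminantMarkers = contaminantMarkers,
                                 immuneMarker = immuneMarker,
                                 fracThreshold = fracThreshold)
  if (length(flagged)) {
    sce <- removeDoubletClusters(sce, sce$cluster, flagged)
    report <- qcReport(sce)
    sce <- stage(sce)
    S4Vectors::metadata(sce)$qc_report <- report
  }
  S4Vectors::metadata(sce)$doublet_clusters <- flagged
  if (!is.null(panel)) {
    ann <- annotateClusters(sce, sce$cluster, panel = panel)
    S4Vectors::metadata(sce)$cluster_annotation <- ann
    sce$cell_type <- unname(ann[as.character(sce$cluster)])
  }
  if (embed)
    sce <- tsneEmbed(sce, perplexity = perplexity, seed = seed)
  sce
}
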