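#' One-vs-rest Kolmogorov-Smirnov test per gene
#'
#' For every gene, the two-sample KS statistic (sup difference of the
#' empirical CDFs, ties handled exactly) between the gene's CPM values in
#' the target cluster and in all other cells, with a two-sided p-value.
#' The statistic is invariant under strictly monotone transforms, so CPM
#' and log CPM give identical statistics. The p-value uses the exact
#' small-sample distribution (conditional on ties) when the smaller group
#' has at most \code{exactLimit} cells, and the asymptotic Kolmogorov
#' tail otherwise.
#'
#' @param sce a \code{SingleCellExperiment} with a \code{cpm} assay.
#' @param labels per-cell cluster labels.
#' @param clusterId the target cluster (must label >= 2 cells, with >= 2
#'   cells remaining outside).
#' @param exactLimit largest smaller-group size for which the exact
#'   p-value is computed (default 25).
#' @param restIds optional restriction of the comparison cells (for
#'   cluster-vs-cluster comparisons); default all other cells.
#' @return a data.frame with columns \code{gene}, \code{ks_statistic},
#'   \code{p_value}.
#' @export
ksOneVsRest <- function(sce, labels, clusterId, exactLimit = 25L,
                        restIds = NULL) {
  labs <- as.character(labels)
  inIdx <- which(labs == as.character(clusterId))
  if (!length(inIdx))
    atlasStop("ks_deg", "unknown cluster id: ", clusterId)
  outIdx <- if (is.null(restIds)) which(labs != as.character(clusterId))
            else which(labs %in% as.character(restIds))
  if (length(inIdx) < 2 || length(outIdx) < 2)
    atlasStop("ks_deg", "need >= 2 cells in the cluster and the rest")
  cpm <- as.matrix(SummarizedExperiment::assay(sce, "cpm"))
  n1 <- length(inIdx); n2 <- length(outIdx)
  useExact <- min(n1, n2) <= exactLimit
  stats <- t(vapply(seq_len(nrow(cpm)), function(g) {
    x <- cpm[g, inIdx]; y <- cpm[g, outIdx]
    D <- ksStatistics(x, y)[["D"]]
    p <- if (useExact)
      stats::psmirnov(D, sizes = c(n1, n2), z = c(x, y),
                      two.sided = TRUE, lower.tail = FALSE, exact = TRUE)
    else ksPValueAsymptotic(D, n1, n2)
    c(D, p)
  }, numeric(2)))
  data.frame(gene = rownames(cpm), ks_statistic = stats[, 1],
             p_value = stats[, 2], stringsAsFactors = FALSE)
}

#' Log2 fold change of mean CPM, cluster vs rest
#'
#' \eqn{\mathrm{lfc}_g = \log_2\left(\frac{\bar{x}_g + \epsilon}
#' {\bar{y}_g + \epsilon}\right)} with means over CPM values and
#' \code{eps} matching the global 0.1 CPM pseudocount.
#'
#' @inheritParams ksOneVsRest
#' @param eps pseudocount on the CPM scale (default 0.1).
#' @return a data.frame with columns \code{gene},
#'   \code{log2_fold_change}.
#' @export
log2FoldChange <- function(sce, labels, clusterId, eps = 0.1,
                           restIds = NULL) {
  labs <- as.character(labels)
  inIdx <- which(labs == as.character(clusterId))
  if (!length(inIdx))
    atlasStop("lfc", "unknown cluster id: ", clusterId)
  outIdx <- if (is.null(restIds)) which(labs != as.character(clusterId))
            else which(labs %in% as.character(restIds))
  cpm <- SummarizedExperiment::assay(sce, "cpm")
  inMean <- Matrix::rowMeans(cpm[, inIdx, drop = FALSE])
  outMean <- Matrix::rowMeans(cpm[, outIdx, drop = FALSE])
  data.frame(gene = rownames(sce),
             log2_fold_change = log2((inMean + eps) / (outMean + eps)),
             stringsAsFactors = FALSE)
}

#' Ranked differential-expression table for a cluster
#'
#' Joins the KS statistic, its p-value and the log2 fold change per gene,
#' keeps upregulated genes (positive fold change) in one-vs-rest mode,
#' sorts by decreasing statistic (ties: increasing p, then decreasing
#' |lfc|, then symbol), and truncates to \code{topN} rows — the schema of
#' published per-cluster marker tables.
#'
#' @inheritParams ksOneVsRest
#' @param topN rows to keep (default 35).
#' @param mode \code{"one_vs_rest"} (default) or
#'   \code{"cluster_vs_cluster"}.
#' @param vs the comparison cluster when
#'   \code{mode = "cluster_vs_cluster"}.
#' @param eps pseudocount for the fold change (default 0.1).
#' @return a data.frame with columns \code{gene}, \code{ks_statistic},
#'   \code{p_value}, \code{log2_fold_change}.
#' @export
degTable <- function(sce, labels, clusterId, topN = 35L,
                     mode = c("one_vs_rest", "cluster_vs_cluster"),
                     vs = NULL, eps = 0.1, exactLimit = 25L) {
  mode <- match.arg(mode)
  if (topN < 1) atlasStop("deg_table", "topN must be >= 1")
  labs <- as.character(labels)
  if (!as.character(clusterId) %in% labs)
    atlasStop("deg_table", "unknown cluster id: ", clusterId)
  restIds <- NULL
  if (mode == "cluster_vs_cluster") {
    if (is.null(vs)) atlasStop("deg_table", "mode needs a vs cluster")
    if (!as.character(vs) %in% labs)
      atlasStop("deg_table", "unknown comparison cluster: ", vs)
    restIds <- vs
  }
  ks <- ksOneVsRest(sce, labels, clusterId, exactLimit = exactLimit,
                    restIds = restIds)
  lfc <- log2FoldChange(sce, labels, clusterId, eps = eps,
                        restIds = restIds)
  tab <- merge(ks, lfc, by = "gene", sort = FALSE)
  if (mode == "one_vs_rest")
    tab <- tab[tab$log2_fold_change > 0, , drop = FALSE]
  ord <- order(-tab$ks_statistic, tab$p_value, -abs(tab$log2_fold_change),
               tab$gene)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  head(tab, topN)
}
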