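#' Filter cells on mapped reads and detected genes
#'
#' Discards cells with fewer than \code{minReads} uniquely mapped reads or
#' fewer than \code{minGenes} detected genes (strict "less than", so a
#' cell exactly at a threshold is retained). A cell failing both filters
#' increments both failure counters but is removed once. The resulting
#' \linkS4class{QCReport} is attached to the returned experiment and
#' available through \code{\link{qcReport}}.
#'
#' @param sce a \code{SingleCellExperiment} with \code{mapped_reads} in its
#'   \code{colData}; detected genes are recomputed from the counts.
#' @param minReads read threshold (default 50000).
#' @param minGenes detected-gene threshold (default 400).
#' @return the filtered \code{SingleCellExperiment}, with
#'   \code{metadata(.)$qc_report} set.
#' @export
filterCells <- function(sce, minReads = 50000L, minGenes = 400L) {
  reads <- sce$mapped_reads
  if (is.null(reads))
    atlasStop("filter_cells", "colData lacks mapped_reads")
  nGenes <- as.integer(Matrix::colSums(
    SummarizedExperiment::assay(sce, "counts") > 0))
  failR <- reads < minReads
  failG <- nGenes < minGenes
  disposition <- rep("pass", ncol(sce))
  disposition[failR & !failG] <- "fail_reads"
  disposition[!failR & failG] <- "fail_genes"
  disposition[failR & failG] <- "fail_both"
  names(disposition) <- colnames(sce)
  report <- methods::new("QCReport",
    nInput = ncol(sce),
    nFailReads = sum(failR),
    nFailGenes = sum(failG),
    nAfterFilters = sum(!failR & !failG),
    nDoubletsRemoved = 0L,
    nFinal = sum(!failR & !failG),
    disposition = disposition)
  out <- sce[, !failR & !failG]
  out$n_genes <- nGenes[!failR & !failG]
  S4Vectors::metadata(out)$qc_report <- report
  out
}

#' Flag clusters of suspected doublets
#'
#' Implements the cluster-level doublet rule: a cluster is flagged when at
#' least \code{fracThreshold} of its cells co-express (raw count > 0) the
#' pan-immune marker and at least one mutually exclusive contaminant
#' lineage marker (epithelial/endothelial/mesenchymal:
#' \code{Epcam}, \code{Cdh5}, \code{Col6a2} by default), or when the
#' cluster's mean CPM of any contaminant marker exceeds that of the immune
#' marker. Both trigger conditions are reported per cluster in the
#' \code{"details"} attribute of the result.
#'
#' @param sce a \code{SingleCellExperiment} with \code{counts} (CPM is
#'   computed on the fly if no \code{cpm} assay is present).
#' @param labels per-cell cluster labels aligned to \code{colnames(sce)}.
#' @param contaminantMarkers contaminant gene symbols; missing symbols are
#'   skipped with a warning, all missing is an error.
#' @param immuneMarker the pan-immune gene (default \code{"Ptprc"}, i.e.
#'   Cd45).
#' @param fracThreshold co-expression fraction required to flag
#'   (default 0.5).
#' @return the flagged cluster labels (possibly empty), with a per-cluster
#'   data.frame in \code{attr(., "details")}.
#' @export
flagDoubletClusters <- function(sce, labels,
                                contaminantMarkers = c("Epcam", "Cdh5",
                                                       "Col6a2"),
                                immuneMarker = "Ptprc",
                                fracThreshold = 0.5) {
  if (length(labels) != ncol(sce))
    atlasStop("flag_doublets", "labels must align to cells")
  present <- contaminantMarkers %in% rownames(sce)
  if (!any(present) || !immuneMarker %in% rownames(sce))
    atlasStop("flag_doublets", "no usable marker genes found in the matrix")
  if (any(!present))
    atlasWarn("flag_doublets", "missing contaminant markers skipped: ",
              paste(contaminantMarkers[!present], collapse = ", "))
  contaminantMarkers <- contaminantMarkers[present]
  counts <- SummarizedExperiment::assay(sce, "counts")
  cpm <- if ("cpm" %in% SummarizedExperiment::assayNames(sce))
    SummarizedExperiment::assay(sce, "cpm") else {
      ls <- Matrix::colSums(counts)
      ls[ls == 0] <- 1
      Matrix::t(Matrix::t(counts) / ls) * 1e6
    }
  labs <- as.character(labels)
  rows <- lapply(unique(labs), function(cl) {
    idx <- which(labs == cl)
    imm <- counts[immuneMarker, idx] > 0
    anyContam <- Matrix::colSums(
      counts[contaminantMarkers, idx, drop = FALSE] > 0) > 0
    fracCo <- mean(imm & anyContam)
    meanImm <- mean(cpm[immuneMarker, idx])
    meanContam <- apply(cpm[contaminantMarkers, idx, drop = FALSE], 1, mean)
    data.frame(cluster = cl, n_cells = length(idx),
               frac_coexpressing = fracCo,
               trigger_coexpression = fracCo >= fracThreshold,
               trigger_cpm = any(meanContam > meanImm),
               stringsAsFactors = FALSE)
  })
  details <- do.call(rbind, rows)
  details$flagged <- details$trigger_coexpression | details$trigger_cpm
  flagged <- details$cluster[details$flagged]
  attr(flagged, "details") <- details
  flagged
}

#' Remove flagged doublet clusters and update the accounting
#'
#' @param sce a filtered \code{SingleCellExperiment} carrying a
#'   \code{qc_report}.
#' @param labels per-cell cluster labels.
#' @param flagged cluster labels to remove (from
#'   \code{\link{flagDoubletClusters}}).
#' @return the experiment without cells of flagged clusters; the attached
#'   \code{QCReport} gains the doublet counts.
#' @export
removeDoubletClusters <- function(sce, labels, flagged) {
  report <- qcReport(sce)
  drop <- as.character(labels) %in% as.character(flagged)
  out <- sce[, !drop]
  if (!is.null(report)) {
    disposition <- report@disposition
    disposition[colnames(sce)[drop]] <- "doublet"
    S4Vectors::metadata(out)$qc_report <- methods::new("QCReport",
      nInput = report@nInput,
      nFailReads = report@nFailReads,
      nFailGenes = report@nFailGenes,
      nAfterFilters = report@nAfterFilters,
      nDoubletsRemoved = report@nDoubletsRemoved + sum(drop),
      nFinal = report@nFinal - sum(drop),
      disposition = disposition)
  }
  out
}

#' Summarize the QC accounting chain
#'
#' Emits the arithmetic chain from input cells through the read/gene
#' filters to the doublet exclusion, asserting internal consistency
#' (\code{n_final = n_after_filters - n_doublets_removed}).
#'
#' @param report a \linkS4class{QCReport}.
#' @return a data.frame with columns \code{stage} and \code{n_cells}.
#' @examples
#' rep <- methods::new("QCReport", nInput = 4500L, nFailReads = 200L,
#'                     nFailGenes = 150L, nAfterFilters = 4199L,
#'                     nDoubletsRemoved = 147L, nFinal = 4052L,
#'                     disposition = character(0))
#' qcAccounting(rep)
#' @export
qcAccounting <- function(report) {
  if (!methods::is(report, "QCReport"))
    atlasStop("qc_accounting", "need a QCReport")
  methods::validObject(report)
  data.frame(
    stage = c("input", "fail_reads", "fail_genes", "after_filters",
              "doublets_removed", "final"),
    n_cells = c(report@nInput, report@nFailReads, report@nFailGenes,
                report@nAfterFilters, report@nDoubletsRemoved,
                report@nFinal))
}
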