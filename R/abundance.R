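#' Population composition across developmental timepoints
#'
#' Counts and percentages of every cell type at every timepoint. The
#' denominator at a timepoint is all annotated cells there
#' (\code{"unassigned"} cells are counted in their own rows but excluded
#' from the denominator); optionally the denominator can be restricted to
#' a subset of types, e.g. the macrophage/monocyte compartment.
#'
#' @param cellTypes per-cell type labels.
#' @param timepoints per-cell timepoints, aligned to \code{cellTypes}.
#' @param denominatorTypes optional character vector restricting both the
#'   reported types and the percentage denominator.
#' @return a data.frame with columns \code{timepoint}, \code{cell_type},
#'   \code{n_cells}, \code{percent}, \code{log10_percent}.
#' @export
compositionOverTime <- function(cellTypes, timepoints,
                                denominatorTypes = NULL) {
  types <- as.character(cellTypes)
  expectedTps <- if (is.factor(timepoints)) levels(timepoints)
                 else unique(as.character(timepoints))
  tps <- as.character(timepoints)
  if (length(types) != length(tps))
    atlasStop("composition", "labels and timepoints must align")
  if (!is.null(denominatorTypes)) {
    keep <- types %in% denominatorTypes
    types <- types[keep]; tps <- tps[keep]
  }
  tpLevels <- intersect(expectedTps, unique(tps))
  empty <- setdiff(expectedTps, tpLevels)
  if (length(empty))
    atlasWarn("composition", "timepoints without cells omitted: ",
              paste(empty, collapse = ", "))
  rows <- list()
  for (tp in tpLevels) {
    sel <- tps == tp
    denom <- sum(sel & types != "unassigned")
    tab <- table(types[sel])
    for (ty in names(tab)) {
      pct <- if (ty == "unassigned" || denom == 0) NA_real_
             else 100 * tab[[ty]] / denom
      rows[[length(rows) + 1]] <- data.frame(
        timepoint = tp, cell_type = ty, n_cells = as.integer(tab[[ty]]),
        percent = pct,
        log10_percent = if (is.na(pct) || pct == 0) NA_real_
                        else log10(pct),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of proliferating macrophage/monocyte cells per timepoint
#'
#' A cell is called proliferative when at least
#' \code{minMarkersDetected} of the proliferation markers have a raw
#' count above zero (detection-based; invariant to CPM scaling). The
#' fraction is computed over the macrophage/monocyte cells of each
#' timepoint.
#'
#' @param sce a \code{SingleCellExperiment} with \code{counts}.
#' @param cellTypes per-cell type labels.
#' @param mmTypes the macrophage/monocyte type names (default Mac I-V).
#' @param prolifMarkers proliferation marker genes
#'   (default \code{Mki67}, \code{Mcm5}); markers missing from the matrix
#'   are skipped with a warning, all missing is an error.
#' @param minMarkersDetected markers required (default 1).
#' @return a data.frame with columns \code{timepoint}, \code{n_mm_cells},
#'   \code{n_proliferating}, \code{fraction}.
#' @export
proliferationFraction <- function(sce, cellTypes,
                                  mmTypes = c("Mac I", "Mac II", "Mac III",
                                              "Mac IV", "Mac V"),
                                  prolifMarkers = c("Mki67", "Mcm5"),
                                  minMarkersDetected = 1L) {
  present <- prolifMarkers %in% rownames(sce)
  if (!any(present))
    atlasStop("proliferation", "no proliferation marker resolves")
  if (any(!present))
    atlasWarn("proliferation", "markers skipped: ",
              paste(prolifMarkers[!present], collapse = ", "))
  prolifMarkers <- prolifMarkers[present]
  counts <- SummarizedExperiment::assay(sce, "counts")
  detected <- Matrix::colSums(
    counts[prolifMarkers, , drop = FALSE] > 0) >= minMarkersDetected
  mm <- as.character(cellTypes) %in% mmTypes
  tps <- as.character(sce$timepoint)
  rows <- lapply(unique(tps), function(tp) {
    sel <- mm & tps == tp
    data.frame(timepoint = tp, n_mm_cells = sum(sel),
               n_proliferating = sum(detected & sel),
               fraction = if (sum(sel)) sum(detected & sel) / sum(sel)
                          else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cumulative germline-identity curves and somatic-hypermutation flag
#'
#' Empirical cumulative distribution of per-cell V and J germline
#' identities (sorted identity against cumulative cell fraction). The
#' hypermutation flag is raised for a locus when its median identity
#' falls below \code{threshold}; identities near 1 throughout indicate no
#' somatic hypermutation.
#'
#' @param table a data.frame with columns \code{v_identity} and
#'   \code{j_identity} (as from \code{\link{generateGermlineTable}}).
#' @param threshold median-identity threshold (default 0.98).
#' @return a list with \code{curves} (data.frame \code{locus},
#'   \code{identity}, \code{cum_fraction}), \code{medians} (named vector)
#'   and \code{shm_flag} (named logical per locus, plus attribute
#'   \code{"any"}).
#' @export
germlineIdentityCdf <- function(table, threshold = 0.98) {
  if (!nrow(table)) atlasStop("germline", "empty identity table")
  loci <- c(v = "v_identity", j = "j_identity")
  curves <- do.call(rbind, lapply(names(loci), function(l) {
    ident <- sort(table[[loci[[l]]]])
    data.frame(locus = toupper(l), identity = ident,
               cum_fraction = seq_along(ident) / length(ident),
               stringsAsFactors = FALSE)
  }))
  medians <- vapply(loci, function(col) median(table[[col]]), numeric(1))
  names(medians) <- toupper(names(loci))
  flag <- medians < threshold
  attr(flag, "any") <- any(flag)
  list(curves = curves, medians = medians, shm_flag = flag)
}
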