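#' Read a count matrix with cell and gene annotations
#'
#' Reads a genes x cells matrix-market sparse integer matrix together with
#' a cell annotation TSV (columns \code{cell_id}, \code{mouse_id},
#' \code{sex}, \code{timepoint}, \code{mapped_reads}; a \code{n_genes}
#' column is accepted but always recomputed from the matrix) and a gene
#' annotation TSV (column \code{gene_symbol}), and returns a validated
#' \link[SingleCellExperiment]{SingleCellExperiment} holding the counts and
#' per-cell metadata.
#'
#' On disk the matrix follows the expression-matrix convention of genes as
#' rows and cells as columns. Gene symbol collisions are resolved by
#' suffixing \code{.1}, \code{.2}, ... with a warning; a missing or empty
#' \code{sex} is stored as \code{"unknown"}.
#'
#' @param matrixPath path to the \code{.mtx} file (genes x cells).
#' @param cellAnnotPath path to the cell annotation TSV (one row per cell,
#'   in matrix column order).
#' @param geneAnnotPath path to the gene annotation TSV (one row per gene,
#'   in matrix row order).
#' @return a \code{SingleCellExperiment} with assay \code{"counts"},
#'   \code{colData} columns \code{cell_id}, \code{mouse_id}, \code{sex},
#'   \code{timepoint}, \code{mapped_reads}, \code{n_genes}.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' sce <- generateAtlas(atlasDesign(cellsPerMouse = 10L, nGenes = 60L,
#'                                  markersPerPopulation = 3L))
#' paths <- writeAtlasCounts(sce, dir)
#' sce2 <- readAtlasCounts(paths$matrix, paths$cells, paths$genes)
#' @export
readAtlasCounts <- function(matrixPath, cellAnnotPath, geneAnnotPath) {
  m <- Matrix::readMM(matrixPath)
  cells <- read.delim(cellAnnotPath, stringsAsFactors = FALSE,
                      check.names = FALSE)
  genes <- read.delim(geneAnnotPath, stringsAsFactors = FALSE,
                      check.names = FALSE)
  if (nrow(genes) != nrow(m))
    atlasStop("read_counts", sprintf(
      "gene annotation '%s' has %d rows but matrix has %d gene rows",
      geneAnnotPath, nrow(genes), nrow(m)))
  if (nrow(cells) != ncol(m))
    atlasStop("read_counts", sprintf(
      "cell annotation '%s' has %d rows but matrix has %d cell columns",
      cellAnnotPath, nrow(cells), ncol(m)))
  vals <- m@x
  if (any(vals < 0))
    atlasStop("read_counts", "matrix contains negative entries")
  if (any(vals != round(vals)))
    atlasStop("read_counts", "matrix contains non-integer entries")
  required <- c("cell_id", "mouse_id", "timepoint", "mapped_reads")
  missing <- setdiff(required, colnames(cells))
  if (length(missing))
    atlasStop("read_counts", "cell annotation lacks columns: ",
              paste(missing, collapse = ", "))
  if (!"gene_symbol" %in% colnames(genes))
    atlasStop("read_counts", "gene annotation lacks column gene_symbol")
  if (anyDuplicated(cells$cell_id))
    atlasStop("read_counts", "cell ids are not unique")
  sex <- if ("sex" %in% colnames(cells)) as.character(cells$sex)
         else rep(NA_character_, nrow(cells))
  sex[is.na(sex) | sex == ""] <- "unknown"
  bad <- !sex %in% c("female", "male", "unknown")
  if (any(bad)) {
    atlasWarn("read_counts", sum(bad),
              " cells with unrecognized sex stored as 'unknown'")
    sex[bad] <- "unknown"
  }
  sym <- as.character(genes$gene_symbol)
  if (anyDuplicated(sym)) {
    atlasWarn("read_counts", "duplicated gene symbols suffixed .1, .2, ...")
    sym <- make.unique(sym, sep = ".")
  }
  m <- methods::as(methods::as(m, "CsparseMatrix"), "dMatrix")
  rownames(m) <- sym
  colnames(m) <- cells$cell_id
  nGenes <- Matrix::colSums(m > 0)
  if ("n_genes" %in% colnames(cells) &&
      any(as.integer(cells$n_genes) != as.integer(nGenes)))
    atlasWarn("read_counts", sum(cells$n_genes != nGenes),
              " cells with annotated n_genes differing from the matrix;",
              " recomputed values used")
  cd <- S4Vectors::DataFrame(
    cell_id = cells$cell_id,
    mouse_id = as.character(cells$mouse_id),
    sex = sex,
    timepoint = as.character(cells$timepoint),
    mapped_reads = as.integer(cells$mapped_reads),
    n_genes = as.integer(nGenes),
    row.names = cells$cell_id)
  extra <- setdiff(colnames(cells), c(colnames(cd), "n_genes"))
  for (col in extra) cd[[col]] <- cells[[col]]
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m),
    colData = cd,
    rowData = S4Vectors::DataFrame(gene_symbol = sym, row.names = sym))
}

#' Write a count experiment as matrix-market plus annotation TSVs
#'
#' Inverse of \code{\link{readAtlasCounts}}: writes \code{matrix.mtx}
#' (genes x cells), \code{cells.tsv} and \code{genes.tsv} into \code{dir}.
#'
#' @param sce a \code{SingleCellExperiment} with a \code{counts} assay.
#' @param dir output directory (created if needed).
#' @return invisibly, a list of the three paths
#'   (\code{matrix}, \code{cells}, \code{genes}).
#' @export
writeAtlasCounts <- function(sce, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(matrix = file.path(dir, "matrix.mtx"),
                cells = file.path(dir, "cells.tsv"),
                genes = file.path(dir, "genes.tsv"))
  m <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(methods::as(methods::as(m, "generalMatrix"),
                              "CsparseMatrix"), paths$matrix)
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  keep <- intersect(c("cell_id", "mouse_id", "sex", "timepoint",
                      "mapped_reads", "n_genes"), colnames(cd))
  writeAtlasTable(cd[, keep, drop = FALSE], paths$cells)
  writeAtlasTable(data.frame(gene_symbol = rownames(sce)), paths$genes)
  invisible(paths)
}

#' Write a tabular result as TSV
#'
#' UTF-8, tab-separated, header row, no quoting or row names; column order
#' is the order of the input. An empty table yields a header-only file.
#'
#' @param table a data.frame (or coercible) with named columns.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeAtlasTable <- function(table, path) {
  table <- as.data.frame(table)
  if (is.null(colnames(table)) || any(colnames(table) == ""))
    atlasStop("write_table", "table must have named columns")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(table, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by \code{\link{writeAtlasTable}}
#'
#' @param path the file path.
#' @return a data.frame.
#' @export
readAtlasTable <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
             encoding = "UTF-8")
}
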