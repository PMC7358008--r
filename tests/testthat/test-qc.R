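test_that("read and gene thresholds use strict less-than removal", {
  counts <- matrix(5L, nrow = 500, ncol = 4)
  counts[401:500, 2] <- 0L              # cell 2: 400 genes detected
  counts[2:500, 3] <- 0L                # cell 3: 1 gene
  sce <- toySCE(counts)
  sce$mapped_reads <- c(49999L, 50000L, 60000L, 50001L)
  out <- filterCells(sce)
  # cell 1 fails reads despite many genes; cell 2 sits exactly on both
  # boundaries and is retained; cell 3 fails genes
  expect_identical(colnames(out), c("c02", "c04"))
  rep <- qcReport(out)
  expect_identical(rep@nFailReads, 1L)
  expect_identical(rep@nFailGenes, 1L)
  expect_identical(rep@nAfterFilters, 2L)
})

test_that("a cell failing both filters is counted twice, removed once", {
  counts <- matrix(0L, nrow = 500, ncol = 2)
  counts[1:450, 1] <- 200L
  counts[1, 2] <- 10L
  sce <- toySCE(counts)
  sce$mapped_reads <- c(90000L, 10L)
  out <- filterCells(sce)
  rep <- qcReport(out)
  expect_identical(rep@nInput, 2L)
  expect_identical(rep@nFailReads, 1L)
  expect_identical(rep@nFailGenes, 1L)
  expect_identical(rep@nAfterFilters, 1L)
  expect_identical(unname(rep@disposition), c("pass", "fail_both"))
})

test_that("filtering is idempotent and dispositions partition the input", {
  sce <- rawAtlasFixture(0L)
  once <- filterCells(sce)
  twice <- filterCells(once)
  expect_identical(colnames(twice), colnames(once))
  rep <- qcReport(once)
  expect_identical(length(rep@disposition), ncol(sce))
  expect_identical(sum(rep@disposition == "pass"), rep@nFinal)
  counted <- sum(rep@disposition %in%
                   c("pass", "fail_reads", "fail_genes", "fail_both"))
  expect_identical(counted, ncol(sce))
})

test_that("low-depth removal count matches the designed fraction", {
  d <- atlasDesign(lowdepthFraction = 0.1, doubletFraction = 0, seed = 0L)
  sce <- generateAtlas(d)
  out <- filterCells(sce)
  removed <- ncol(sce) - ncol(out)
  # binomial error around 200 of 2000
  expect_lt(abs(removed - 200), 4 * sqrt(2000 * 0.1 * 0.9))
})

test_that("doublet clusters are flagged and clean clusters are not", {
  sce <- pipelineFixture(0L)
  # the pipeline fixture already removed one flagged cluster; re-derive a
  # provisional clustering on the raw data to exercise the rule directly
  raw <- filterCells(rawAtlasFixture(0L))
  raw <- cpmNormalize(raw)
  feats <- fanoFeatureSelect(raw)
  raw <- pcaProject(raw, feats)
  g <- buildKnnGraph(raw, k = 15)
  labels <- leidenCluster(g, resolution = 0.4, seed = 0L)
  flagged <- flagDoubletClusters(raw, labels)
  details <- attr(flagged, "details")
  truthDoublet <- vapply(split(raw$is_doublet, labels), mean, numeric(1))
  doubletCluster <- names(truthDoublet)[truthDoublet > 0.9]
  expect_true(all(doubletCluster %in% flagged))
  clean <- names(truthDoublet)[truthDoublet < 0.05]
  expect_false(any(clean %in% flagged))
})

test_that("pure immune cluster with zero contaminant counts is not flagged", {
  counts <- matrix(0L, nrow = 5, ncol = 10)
  rownames(counts) <- c("Ptprc", "Epcam", "Cdh5", "Col6a2", "Actb")
  counts["Ptprc", ] <- 50L
  counts["Actb", ] <- 100L
  sce <- toySCE(counts)
  flagged <- flagDoubletClusters(sce, rep("k0", 10))
  expect_length(flagged, 0)
})

test_that("fracThreshold = 1 spares a cluster with one clean cell", {
  counts <- matrix(0L, nrow = 3, ncol = 4)
  rownames(counts) <- c("Ptprc", "Epcam", "Actb")
  counts["Ptprc", ] <- 10L
  counts["Epcam", 1:3] <- 8L    # one cell lacks the contaminant
  counts["Actb", ] <- 60L       # keeps immune CPM above contaminant CPM
  sce <- toySCE(counts)
  flagged <- flagDoubletClusters(sce, rep("k0", 4),
                                 contaminantMarkers = "Epcam",
                                 fracThreshold = 1)
  expect_length(flagged, 0)
})

test_that("missing markers are skipped with warning, all missing errors", {
  counts <- matrix(1L, nrow = 2, ncol = 4)
  rownames(counts) <- c("Ptprc", "Epcam")
  sce <- toySCE(counts)
  expect_warning(
    flagDoubletClusters(sce, rep("k0", 4),
                        contaminantMarkers = c("Epcam", "NotAGene")),
    "NotAGene")
  expect_error(
    flagDoubletClusters(sce, rep("k0", 4),
                        contaminantMarkers = "NotAGene"),
    "no usable marker")
})

test_that("qc accounting reproduces the arithmetic chain and rejects
           inconsistent reports", {
  rep <- methods::new("QCReport", nInput = 4500L, nFailReads = 200L,
                      nFailGenes = 150L, nAfterFilters = 4199L,
                      nDoubletsRemoved = 147L, nFinal = 4052L,
                      disposition = character(0))
  tab <- qcAccounting(rep)
  expect_identical(tab$n_cells[tab$stage == "final"], 4052L)
  # zero removals: final equals input
  rep0 <- methods::new("QCReport", nInput = 10L, nFailReads = 0L,
                       nFailGenes = 0L, nAfterFilters = 10L,
                       nDoubletsRemoved = 0L, nFinal = 10L,
                       disposition = character(0))
  expect_identical(qcAccounting(rep0)$n_cells[6], 10L)
  # removing more doublets than cells is inconsistent
  expect_error(methods::new("QCReport", nInput = 10L, nFailReads = 0L,
                            nFailGenes = 0L, nAfterFilters = 5L,
                            nDoubletsRemoved = 6L, nFinal = -1L,
                            disposition = character(0)))
})
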