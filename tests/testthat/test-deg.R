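test_that("a perfectly separating gene reaches statistic 1 and disjoint
           supports are equivalent to statistic 1", {
  set.seed(21)
  counts <- matrix(rpois(20 * 30, 5) + 1L, nrow = 20, ncol = 30)
  counts[1, 1:8] <- 50L     # gene 1 positive in cluster A ...
  counts[1, 9:30] <- 0L     # ... zero everywhere else
  sce <- cpmNormalize(toySCE(counts))
  labels <- rep(c("A", "rest"), c(8, 22))
  ks <- ksOneVsRest(sce, labels, "A")
  expect_identical(ks$ks_statistic[1], 1)
  # statistic 1 implies disjoint supports and vice versa
  cpm <- as.matrix(SummarizedExperiment::assay(sce, "cpm"))
  for (g in seq_len(nrow(sce))) {
    disjoint <- max(cpm[g, 1:8]) < min(cpm[g, 9:30]) ||
      max(cpm[g, 9:30]) < min(cpm[g, 1:8])
    expect_identical(ks$ks_statistic[g] == 1, disjoint)
  }
})

test_that("identical distributions give statistic 0 and toy groups match
           the frozen brute-force values", {
  counts <- matrix(0L, nrow = 2, ncol = 6)
  counts[1, ] <- c(1L, 2L, 3L, 4L, 5L, 6L)
  counts[2, ] <- 7L
  sce <- toySCE(counts)
  # bypass normalization: inject raw values as the cpm assay
  SummarizedExperiment::assay(sce, "cpm", withDimnames = FALSE) <-
    matrix(c(1, 2, 3, 4, 5, 6, rep(7, 6)), nrow = 2, byrow = TRUE,
           dimnames = dimnames(SummarizedExperiment::assay(sce)))
  ksA <- ksOneVsRest(sce, rep(c("a", "b"), each = 3), "a")
  expect_identical(ksA$ks_statistic[1], 1)       # {1,2,3} vs {4,5,6}
  expect_identical(ksA$ks_statistic[2], 0)       # constant gene
  ksB <- ksOneVsRest(sce, rep(c("a", "b"), 3), "a")
  expect_equal(ksB$ks_statistic[1], 1 / 3)       # {1,3,5} vs {2,4,6}
})

test_that("implementation agrees with the brute-force CDF oracle to
           1e-12 on random small instances", {
  set.seed(77)
  for (i in 1:100) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    x <- sample(0:8, n1, replace = TRUE) + rbinom(n1, 1, 0.5) * 0.5
    y <- sample(0:8, n2, replace = TRUE)
    D <- lungatlas:::ksStatistics(x, y)[["D"]]
    expect_equal(D, ksBruteForce(x, y), tolerance = 1e-12)
  }
})

test_that("p-values match stats::ks.test in both regimes", {
  set.seed(31)
  # exact regime (small groups, no ties)
  x <- rnorm(10); y <- rnorm(12, 0.5)
  counts <- matrix(1L, nrow = 1, ncol = 22)
  sce <- toySCE(counts)
  SummarizedExperiment::assay(sce, "cpm", withDimnames = FALSE) <-
    matrix(c(x, y), nrow = 1)
  ks <- ksOneVsRest(sce, rep(c("a", "b"), c(10, 12)), "a")
  ref <- stats::ks.test(x, y, exact = TRUE)
  expect_equal(ks$p_value[1], ref$p.value, tolerance = 1e-10)
  # asymptotic regime
  x2 <- rnorm(60); y2 <- rnorm(60, 0.3)
  sce2 <- toySCE(matrix(1L, nrow = 1, ncol = 120))
  SummarizedExperiment::assay(sce2, "cpm", withDimnames = FALSE) <-
    matrix(c(x2, y2), nrow = 1)
  ks2 <- ksOneVsRest(sce2, rep(c("a", "b"), c(60, 60)), "a")
  ref2 <- stats::ks.test(x2, y2, exact = FALSE)
  expect_equal(ks2$p_value[1], ref2$p.value, tolerance = 1e-6)
})

test_that("the statistic is invariant under monotone transforms of
           expression", {
  sce <- smallAtlasFixture()
  labels <- sce$true_population
  ksCpm <- ksOneVsRest(sce, labels, "Pop01")
  sceLog <- sce
  SummarizedExperiment::assay(sceLog, "cpm", withDimnames = FALSE) <-
    log10(as.matrix(SummarizedExperiment::assay(sce, "cpm")) + 0.1)
  ksLog <- ksOneVsRest(sceLog, labels, "Pop01")
  expect_equal(ksCpm$ks_statistic, ksLog$ks_statistic, tolerance = 1e-12)
})

test_that("log2 fold change follows the pseudocount formula and is
           antisymmetric", {
  counts <- matrix(0L, nrow = 2, ncol = 12)
  sce <- toySCE(counts)
  cpm <- matrix(0, nrow = 2, ncol = 12)
  cpm[1, 1:6] <- 819.1
  cpm[2, ] <- 100
  SummarizedExperiment::assay(sce, "cpm", withDimnames = FALSE) <- cpm
  labels <- rep(c("a", "b"), each = 6)
  lfc <- log2FoldChange(sce, labels, "a")
  expect_equal(lfc$log2_fold_change[1], log2(819.2 / 0.1))
  expect_equal(lfc$log2_fold_change[1], 13, tolerance = 1e-4)
  expect_equal(lfc$log2_fold_change[2], 0)
  lfcB <- log2FoldChange(sce, labels, "b")
  expect_equal(lfcB$log2_fold_change, -lfc$log2_fold_change)
})

test_that("deg tables rank planted markers on top and honour modes", {
  sce <- pipelineFixture(0L)
  tab <- degTable(sce, sce$cell_type, "Mast", topN = 20L)
  rd <- SummarizedExperiment::rowData(sce)
  mastMarkers <- rownames(sce)[rd$marker_of == "Mast"]
  expect_gte(mean(tab$gene %in% mastMarkers), 0.8)
  expect_true(all(diff(tab$ks_statistic) <= 0))
  expect_true(all(tab$log2_fold_change > 0))
  # exactly topN rows when enough upregulated genes exist
  tab35 <- degTable(sce, sce$cell_type, "B", topN = 35L)
  expect_identical(nrow(tab35), 35L)
  expect_error(degTable(sce, sce$cell_type, "NoSuchCluster"), "unknown")
})

test_that("cluster-vs-cluster mode with mirrored clusters gives all-zero
           statistics", {
  set.seed(12)
  counts <- matrix(rpois(30 * 10, 6), nrow = 30, ncol = 10)
  dup <- cbind(counts, counts)
  sce <- cpmNormalize(toySCE(dup))
  labels <- rep(c("a", "b"), each = 10)
  tab <- degTable(sce, labels, "a", topN = 30L,
                  mode = "cluster_vs_cluster", vs = "b")
  expect_true(all(tab$ks_statistic == 0))
  expect_error(degTable(sce, labels, "a", mode = "cluster_vs_cluster"),
               "vs cluster")
})
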