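test_that("knn graph ties break by ascending index and degrees reach k", {
  # "a" is exactly equidistant (distance 5) from "b" and "c"; with the
  # ascending-index tie-break it picks "b", so the union graph is the
  # path b-a, a-c (c picks a, its unique nearest)
  pts <- rbind(a = c(0, 0), b = c(5, 0), c = c(0, 5))
  g <- buildKnnGraph(pts, k = 1)
  expect_equal(igraph::ecount(g), 2)
  expect_true(igraph::are_adjacent(g, "a", "b"))
  expect_true(igraph::are_adjacent(g, "a", "c"))
  expect_false(igraph::are_adjacent(g, "b", "c"))
  # union property on random coordinates
  set.seed(3)
  coords <- matrix(rnorm(50 * 4), 50, 4)
  g2 <- buildKnnGraph(coords, k = 6)
  expect_true(all(igraph::degree(g2) >= 6))
  expect_error(buildKnnGraph(coords, k = 50), "below")
})

test_that("well-separated blobs get no cross-blob edges", {
  set.seed(4)
  blobA <- matrix(rnorm(30 * 3, 0, 0.2), 30, 3)
  blobB <- matrix(rnorm(30 * 3, 50, 0.2), 30, 3)
  g <- buildKnnGraph(rbind(blobA, blobB), k = 5)
  el <- igraph::as_edgelist(g, names = FALSE)
  cross <- xor(el[, 1] <= 30, el[, 2] <= 30)
  expect_identical(sum(cross), 0L)
})

test_that("leiden separates disconnected cliques and is deterministic", {
  g <- igraph::disjoint_union(igraph::make_full_graph(10),
                              igraph::make_full_graph(6))
  igraph::V(g)$name <- paste0("v", 1:16)
  labels <- leidenCluster(g, resolution = 0.5, seed = 1L)
  expect_identical(length(unique(labels)), 2L)
  expect_identical(length(unique(labels[1:10])), 1L)
  expect_identical(length(unique(labels[11:16])), 1L)
  # labels are size-ordered contiguous integers from 0
  expect_identical(sort(unique(unname(labels))), c(0L, 1L))
  expect_identical(unname(labels[1]), 0L)
  expect_identical(labels, leidenCluster(g, resolution = 0.5, seed = 1L))
  expect_error(leidenCluster(igraph::make_empty_graph(0), 1, 1L), "empty")
})

test_that("clustering is stable under cell permutation up to relabeling", {
  sce <- pipelineFixture(0L)
  pc <- SingleCellExperiment::reducedDim(sce, "PCA")
  g <- buildKnnGraph(pc, k = 15)
  lab <- leidenCluster(g, resolution = 0.4, seed = 0L)
  set.seed(99)
  perm <- sample(nrow(pc))
  g2 <- buildKnnGraph(pc[perm, ], k = 15)
  lab2 <- leidenCluster(g2, resolution = 0.4, seed = 0L)
  # same partition: compare co-membership via ARI
  expect_equal(mclust::adjustedRandIndex(lab[perm], lab2), 1)
})

test_that("tsne is seed-deterministic, separates populations, and
           validates perplexity", {
  sce <- smallAtlasFixture()
  feats <- suppressWarnings(fanoFeatureSelect(sce, nFeatures = 100L))
  sce <- pcaProject(sce, feats, k = 10)
  e1 <- tsneEmbed(SingleCellExperiment::reducedDim(sce, "PCA"),
                  perplexity = 15, seed = 3L, maxIter = 300)
  e2 <- tsneEmbed(SingleCellExperiment::reducedDim(sce, "PCA"),
                  perplexity = 15, seed = 3L, maxIter = 300)
  expect_identical(e1, e2)
  pop <- sce$true_population
  d <- as.matrix(dist(e1))
  same <- d[outer(pop, pop, "==") & upper.tri(d)]
  diffr <- d[outer(pop, pop, "!=") & upper.tri(d)]
  expect_gt(mean(diffr), mean(same))
  expect_error(tsneEmbed(matrix(rnorm(20), 10, 2), perplexity = 5),
               "perplexity")
})

test_that("marker-panel annotation names planted clusters correctly", {
  sce <- pipelineFixture(0L)
  ann <- S4Vectors::metadata(sce)$cluster_annotation
  # every planted population name is assigned to exactly one cluster
  expect_setequal(unname(ann), rownames(defaultComposition()))
  # per-cell agreement with the planted truth
  agree <- mean(sce$cell_type == sce$true_population)
  expect_gte(agree, 0.95)
})

test_that("annotation falls back to unassigned and breaks ties by panel
           order", {
  counts <- matrix(0L, nrow = 3, ncol = 6,
                   dimnames = list(c("Gal", "Itgax", "Actb"), NULL))
  counts["Actb", ] <- 50L
  sce <- cpmNormalize(toySCE(counts))
  ann <- annotateClusters(sce, rep("k", 6),
                          panel = list(A = c(Gal = 1), B = c(Itgax = 1)))
  expect_identical(unname(ann), "unassigned")
  counts2 <- counts
  counts2["Gal", ] <- 5L
  counts2["Itgax", ] <- 5L
  sce2 <- cpmNormalize(toySCE(counts2))
  expect_warning(
    ann2 <- annotateClusters(sce2, rep("k", 6),
                             panel = list(A = c(Gal = 1),
                                          B = c(Itgax = 1))),
    "tie")
  expect_identical(unname(ann2), "A")
})

test_that("dot-plot summaries cover the grid with correct fractions", {
  sce <- pipelineFixture(0L)
  genes <- c("Gal", "Mcpt4", "Ms4a1")
  dp <- dotplotSummary(sce, sce$cell_type, genes)
  expect_identical(nrow(dp),
                   length(genes) * length(unique(sce$cell_type)))
  expect_true(all(dp$frac_expressing >= 0 & dp$frac_expressing <= 1))
  home <- c(Gal = "Mac I", Mcpt4 = "Mast", Ms4a1 = "B")
  for (g in genes) {
    inHome <- dp$frac_expressing[dp$gene == g & dp$cluster == home[[g]]]
    away <- dp$frac_expressing[dp$gene == g & dp$cluster != home[[g]]]
    expect_gte(inHome, 0.8)
    expect_true(all(away <= 0.3))
  }
  # absent vs ubiquitous gene on a toy matrix: exact frac and log floor
  counts <- matrix(c(0L, 0L, 0L, 4L, 6L, 8L), nrow = 2, byrow = TRUE,
                   dimnames = list(c("off", "on"), NULL))
  toy <- cpmNormalize(toySCE(counts))
  dp2 <- dotplotSummary(toy, rep("k", 3), c("off", "on"))
  expect_identical(dp2$frac_expressing[dp2$gene == "off"], 0)
  expect_equal(dp2$mean_log_expression[dp2$gene == "off"], -1)
  expect_identical(dp2$frac_expressing[dp2$gene == "on"], 1)
})
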