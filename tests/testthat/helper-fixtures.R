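# Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

# Full default synthetic atlas run through the pipeline, per seed.
pipelineFixture <- function(seed = 0L) {
  key <- paste0("pipeline", seed)
  if (is.null(.fixtureCache[[key]])) {
    sce <- generateAtlas(atlasDesign(seed = seed))
    .fixtureCache[[key]] <- suppressWarnings(
      runAtlasPipeline(sce, seed = seed))
  }
  .fixtureCache[[key]]
}

# Raw (unfiltered) default atlas, per seed.
rawAtlasFixture <- function(seed = 0L) {
  key <- paste0("raw", seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- generateAtlas(atlasDesign(seed = seed))
  .fixtureCache[[key]]
}

# A small normalized experiment for cheap unit tests.
smallAtlasFixture <- function() {
  if (is.null(.fixtureCache$small)) {
    d <- atlasDesign(nPopulations = 4L, markersPerPopulation = 5L,
                     nGenes = 200L, cellsPerMouse = 30L,
                     doubletFraction = 0, lowdepthFraction = 0, seed = 11L)
    .fixtureCache$small <- cpmNormalize(generateAtlas(d))
  }
  .fixtureCache$small
}

# Independent brute-force two-sample KS oracle: evaluate both empirical
# CDFs at every pooled point and take the sup gap.
ksBruteForce <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  f1 <- vapply(pts, function(t) mean(x <= t), numeric(1))
  f2 <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(f1 - f2))
}

# Build a tiny SingleCellExperiment from a dense genes x cells count
# matrix (cells get minimal metadata).
toySCE <- function(counts, mouse = NULL, timepoint = "P1") {
  nG <- nrow(counts); nC <- ncol(counts)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("g%02d", 1:nG)
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("c%02d", 1:nC)
  if (is.null(mouse)) mouse <- rep(c("mA", "mB"), length.out = nC)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
    colData = S4Vectors::DataFrame(
      cell_id = colnames(counts),
      mouse_id = mouse,
      sex = rep("unknown", nC),
      timepoint = rep(timepoint, length.out = nC),
      mapped_reads = as.integer(colSums(counts)),
      n_genes = as.integer(colSums(counts > 0)),
      row.names = colnames(counts)))
  sce
}
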