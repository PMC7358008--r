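#' Sample embedded distances of same-mouse and different-mouse cell pairs
#'
#' Within one (cell type, timepoint) stratum, draws \code{nPairs} pairs of
#' distinct cells from a single mouse and \code{nPairs} pairs spanning two
#' mice, and returns their Euclidean distances in the 2-D embedding.
#' Pairs are sampled uniformly over the respective pair sets, with
#' replacement across draws (a small stratum may not have \code{nPairs}
#' distinct pairs). A stratum needs at least 2 cells from each of at least
#' 2 mice; otherwise \code{NULL} is returned (reported downstream as
#' \code{insufficient_cells}).
#'
#' @param embedding n x 2 coordinate matrix of the stratum's cells.
#' @param mouse per-cell mouse ids aligned to the embedding rows.
#' @param nPairs pairs per distribution (default 100).
#' @param seed integer seed.
#' @return \code{list(same = , diff = )} of distance vectors, or
#'   \code{NULL} when the stratum is insufficient.
#' @export
samplePairDistances <- function(embedding, mouse, nPairs = 100L,
                                seed = 0L) {
  mouse <- as.character(mouse)
  sizes <- table(mouse)
  if (length(sizes) < 2 || any(sizes < 2)) return(NULL)
  eligible <- names(sizes)
  withSeed(seed, {
    # same-mouse pairs, uniform over all within-mouse distinct pairs
    nw <- sizes[eligible] * (sizes[eligible] - 1) / 2
    same <- vapply(seq_len(nPairs), function(i) {
      m <- sample(eligible, 1, prob = nw)
      ij <- sample(which(mouse == m), 2, replace = FALSE)
      sqrt(sum((embedding[ij[1], ] - embedding[ij[2], ])^2))
    }, numeric(1))
    # different-mouse pairs, uniform over cross-mouse pairs (rejection)
    n <- nrow(embedding)
    diff <- vapply(seq_len(nPairs), function(i) {
      repeat {
        ij <- sample.int(n, 2, replace = FALSE)
        if (mouse[ij[1]] != mouse[ij[2]]) break
      }
      sqrt(sum((embedding[ij[1], ] - embedding[ij[2], ])^2))
    }, numeric(1))
    list(same = same, diff = diff)
  })
}

#' Compare same-mouse and different-mouse distance distributions
#'
#' Two-sample Kolmogorov-Smirnov comparison of the two distance
#' distributions. The reported statistic is the two-sided sup difference
#' of the empirical CDFs; the p-value is one-sided for the direction the
#' test screens for (different-mouse distances stochastically longer), so
#' that under exchangeable mice the flag rate matches \code{alpha}. The
#' verdict is \code{"batch_effect"} when \code{p < alpha}.
#'
#' @param same,diff distance vectors (non-empty).
#' @param alpha significance level (default 0.05).
#' @param cellType,timepoint stratum labels carried into the result.
#' @return a \linkS4class{PairDistanceResult}.
#' @export
compareDistanceCdfs <- function(same, diff, alpha = 0.05,
                                cellType = NA_character_,
                                timepoint = NA_character_) {
  if (!length(same) || !length(diff))
    atlasStop("batch_check", "empty distance list")
  ks <- ksStatistics(same, diff)
  p <- ksPValueOneSided(ks[["Dplus"]], length(same), length(diff))
  methods::new("PairDistanceResult",
    cellType = as.character(cellType),
    timepoint = as.character(timepoint),
    sameDistances = same, diffDistances = diff,
    statistic = ks[["D"]],
    pValue = p,
    verdict = if (p < alpha) "batch_effect" else "no_batch_effect")
}

#' Mouse-variation pair-distance test across all strata
#'
#' Runs the same-mouse vs different-mouse pair-distance comparison for
#' every (cell type, timepoint) stratum, using distances in the 2-D t-SNE
#' embedding (or, optionally, the first two PCs). Different-mouse pairs
#' are drawn within a timepoint, matching the question of variation
#' between the replicate mice at each stage.
#'
#' @param sce a \code{SingleCellExperiment} with the chosen embedding and
#'   \code{mouse_id}/\code{timepoint} in \code{colData}.
#' @param cellTypes per-cell type labels (cluster annotations).
#' @param nPairs pairs per distribution (default 100).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed.
#' @param useEmbedding reduced dimension to measure distances in
#'   (default \code{"TSNE"}).
#' @return a data.frame with one row per stratum (cell type, timepoint,
#'   n_cells, ks_statistic, p_value, verdict); the
#'   \linkS4class{PairDistanceResult} objects, which carry the sampled
#'   distances for CDF plotting, are in \code{attr(., "results")}.
#' @export
batchEffectTest <- function(sce, cellTypes, nPairs = 100L, alpha = 0.05,
                            seed = 0L, useEmbedding = "TSNE") {
  emb <- SingleCellExperiment::reducedDim(sce, useEmbedding)[, 1:2,
                                                             drop = FALSE]
  types <- as.character(cellTypes)
  tps <- as.character(sce$timepoint)
  strata <- unique(data.frame(type = types, tp = tps,
                              stringsAsFactors = FALSE))
  strata <- strata[order(strata$type, strata$tp), ]
  results <- list()
  rows <- list()
  for (s in seq_len(nrow(strata))) {
    idx <- which(types == strata$type[s] & tps == strata$tp[s])
    pairs <- samplePairDistances(emb[idx, , drop = FALSE],
                                 sce$mouse_id[idx], nPairs = nPairs,
                                 seed = seed + s)
    res <- if (is.null(pairs)) {
      methods::new("PairDistanceResult",
        cellType = strata$type[s], timepoint = strata$tp[s],
        sameDistances = numeric(0), diffDistances = numeric(0),
        statistic = NA_real_, pValue = NA_real_,
        verdict = "insufficient_cells")
    } else {
      compareDistanceCdfs(pairs$same, pairs$diff, alpha = alpha,
                          cellType = strata$type[s],
                          timepoint = strata$tp[s])
    }
    results[[s]] <- res
    rows[[s]] <- data.frame(
      cell_type = strata$type[s], timepoint = strata$tp[s],
      n_cells = length(idx), ks_statistic = res@statistic,
      p_value = res@pValue, verdict = res@verdict,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "results") <- results
  out
}

#' Empirical CDFs of a pair-distance result, for plotting
#'
#' @param result a \linkS4class{PairDistanceResult}.
#' @return a data.frame with columns \code{group}, \code{distance},
#'   \code{cum_fraction}.
#' @export
pairDistanceCdf <- function(result) {
  mk <- function(d, g) {
    d <- sort(d)
    data.frame(group = g, distance = d,
               cum_fraction = seq_along(d) / length(d),
               stringsAsFactors = FALSE)
  }
  rbind(mk(result@sameDistances, "same_mouse"),
        mk(result@diffDistances, "different_mouse"))
}
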