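#' Diffusion pseudotime from a root cell
#'
#' Orders cells along an inferred developmental progression. The
#' symmetrized kNN graph (restricted to the requested cells) defines a
#' random-walk transition matrix; its spectral decomposition gives
#' diffusion components, and each cell's pseudotime is its diffusion
#' distance to the root cell,
#' \eqn{\mathrm{dpt}(x)^2 = \sum_{i \ge 2}
#' \left(\frac{\lambda_i}{1 - \lambda_i}\right)^2
#' (\psi_i(x) - \psi_i(\mathrm{root}))^2},
#' min-max scaled to [0, 1] over the root's connected component. Cells off
#' that component get \code{NA} and are flagged.
#'
#' @param sce a \code{SingleCellExperiment} with a \code{"PCA"} reduced
#'   dimension, or a PC coordinate matrix with named rows.
#' @param rootCell cell identifier of the starting cell (pseudotime 0).
#' @param cells optional subset of cell identifiers to order (the cluster
#'   subset of interest); default all cells. Must contain the root.
#' @param k neighbors for the kNN graph over the subset (default 15,
#'   reduced for small subsets).
#' @return a named numeric vector of pseudotimes over \code{cells}
#'   (\code{NA} off the root's component), with the root id in
#'   \code{attr(., "root")} and any disconnected cells in
#'   \code{attr(., "disconnected")}.
#' @export
computePseudotime <- function(sce, rootCell, cells = NULL, k = 15L) {
  coords <- if (is.matrix(sce)) sce else
    SingleCellExperiment::reducedDim(sce, "PCA")
  if (is.null(rownames(coords)))
    rownames(coords) <- if (is.matrix(sce)) as.character(seq_len(nrow(sce)))
                        else colnames(sce)
  if (is.null(cells)) cells <- rownames(coords)
  if (!rootCell %in% cells)
    atlasStop("pseudotime", "root cell is not in the requested subset")
  coords <- coords[cells, , drop = FALSE]
  n <- nrow(coords)
  pt <- setNames(rep(NA_real_, n), cells)
  if (n == 1) {
    pt[] <- 0
    attr(pt, "root") <- rootCell
    attr(pt, "disconnected") <- character(0)
    return(pt)
  }
  g <- buildKnnGraph(coords, k = min(k, n - 1L))
  comp <- igraph::components(g)$membership
  rootComp <- comp[[rootCell]]
  on <- names(comp)[comp == rootComp]
  disconnected <- setdiff(cells, on)
  A <- igraph::as_adjacency_matrix(
    igraph::induced_subgraph(g, on), sparse = FALSE)
  m <- nrow(A)
  if (m == 1) {
    pt[on] <- 0
  } else {
    d <- rowSums(A)
    dis <- 1 / sqrt(d)
    S <- A * outer(dis, dis)          # D^{-1/2} A D^{-1/2}, symmetric
    es <- eigen(S, symmetric = TRUE)
    lambda <- es$values
    psi <- es$vectors * dis           # right eigenvectors of D^{-1} A
    use <- which(lambda < 1 - 1e-8 & lambda > -1 + 1e-8)
    w <- lambda[use] / (1 - lambda[use])
    rootIdx <- match(rootCell, rownames(A))
    delta <- sweep(psi[, use, drop = FALSE], 2,
                   psi[rootIdx, use], "-")
    dpt <- sqrt(rowSums(sweep(delta, 2, w, "*")^2))
    rng <- range(dpt)
    pt[rownames(A)] <- if (rng[2] > rng[1])
      (dpt - rng[1]) / (rng[2] - rng[1]) else 0
  }
  attr(pt, "root") <- rootCell
  attr(pt, "disconnected") <- disconnected
  pt
}

#' Pseudotime analysis of a cluster subset
#'
#' The standard trajectory flow for a subset of interest (e.g. one
#' macrophage population): re-normalize the subset, re-select features on
#' it (excluding proliferation/cell-cycle genes, whose binary axis would
#' otherwise dominate the subset geometry), re-project onto principal
#' components, pick the root as the cell with the highest early-marker
#' score, and compute diffusion pseudotime.
#'
#' @param sce a \code{SingleCellExperiment} with \code{counts}.
#' @param cells cell identifiers of the subset.
#' @param earlyMarkers genes marking the start of the trajectory.
#' @param excludeGenes genes excluded from feature selection
#'   (default \code{c("Mki67", "Mcm5")}).
#' @param nPCs principal components for the subset (default 10).
#' @param k kNN-graph neighbors for the diffusion (default 30).
#' @param nFeatures subset features (default 500).
#' @return the pseudotime vector of \code{\link{computePseudotime}}, with
#'   the subset experiment in \code{attr(., "experiment")}.
#' @export
pseudotimeOnSubset <- function(sce, cells, earlyMarkers,
                               excludeGenes = c("Mki67", "Mcm5"),
                               nPCs = 10L, k = 30L, nFeatures = 500L) {
  sub <- suppressWarnings(cpmNormalize(sce[, cells]))
  feats <- suppressWarnings(
    fanoFeatureSelect(sub, nFeatures = nFeatures,
                      excludeGenes = excludeGenes))
  sub <- pcaProject(sub, feats,
                    k = min(nPCs, length(selectedGenes(feats))))
  root <- selectRootCell(sub, earlyMarkers)
  pt <- computePseudotime(sub, root, k = k)
  attr(pt, "experiment") <- sub
  pt
}

#' Pick a root cell by an early-marker score
#'
#' The cell (within the optional subset) with the highest mean log CPM of
#' the given early marker genes.
#'
#' @param sce a \code{SingleCellExperiment} with a \code{logcpm} assay.
#' @param earlyMarkers gene symbols marking the start of the trajectory.
#' @param cells optional subset of cell ids.
#' @return a cell identifier.
#' @export
selectRootCell <- function(sce, earlyMarkers, cells = NULL) {
  genes <- intersect(earlyMarkers, rownames(sce))
  if (!length(genes))
    atlasStop("pseudotime", "no early marker resolves")
  if (is.null(cells)) cells <- colnames(sce)
  score <- colMeans(SummarizedExperiment::assay(sce, "logcpm")[genes,
                      cells, drop = FALSE])
  cells[which.max(score)]
}

#' Interpolate pseudotime as a scalar potential on a grid
#'
#' Lays a regular \code{nx} x \code{ny} lattice over the bounding box of
#' the embedding. A node is populated when at least one cell lies within
#' \code{radiusFactor} times the grid spacing; its potential is the
#' inverse-distance-weighted mean of the pseudotimes of the cells within
#' that radius (a cell sitting exactly on a node contributes its value
#' directly).
#'
#' @param embedding n x 2 cell coordinates.
#' @param pseudotime per-cell pseudotime aligned to the embedding rows;
#'   cells with \code{NA} are ignored.
#' @param nx,ny grid resolution (default 50 x 50).
#' @param radiusFactor population radius in units of grid spacing
#'   (default 1.5).
#' @return a \linkS4class{PotentialField}.
#' @export
interpolatePotential <- function(embedding, pseudotime, nx = 50L,
                                 ny = 50L, radiusFactor = 1.5) {
  keep <- !is.na(pseudotime)
  emb <- embedding[keep, , drop = FALSE]
  pt <- pseudotime[keep]
  if (nrow(emb) < 1)
    atlasStop("potential", "no cells with pseudotime")
  rx <- range(emb[, 1]); ry <- range(emb[, 2])
  if (rx[1] == rx[2] && ry[1] == ry[2])
    atlasStop("potential", "degenerate bounding box: all cells identical")
  gx <- if (rx[1] < rx[2]) seq(rx[1], rx[2], length.out = nx)
        else rep(rx[1], nx)
  gy <- if (ry[1] < ry[2]) seq(ry[1], ry[2], length.out = ny)
        else rep(ry[1], ny)
  hx <- if (nx > 1 && rx[1] < rx[2]) diff(rx) / (nx - 1) else 0
  hy <- if (ny > 1 && ry[1] < ry[2]) diff(ry) / (ny - 1) else 0
  radius <- radiusFactor * max(hx, hy)
  pot <- matrix(NA_real_, nx, ny)
  popd <- matrix(FALSE, nx, ny)
  for (i in seq_len(nx)) {
    dx2 <- (emb[, 1] - gx[i])^2
    for (j in seq_len(ny)) {
      d <- sqrt(dx2 + (emb[, 2] - gy[j])^2)
      within <- which(d <= radius)
      if (!length(within)) next
      popd[i, j] <- TRUE
      hits <- within[d[within] < 1e-12]
      pot[i, j] <- if (length(hits)) mean(pt[hits]) else {
        w <- 1 / d[within]
        sum(w * pt[within]) / sum(w)
      }
    }
  }
  methods::new("PotentialField",
    x = gx, y = gy, potential = pot, populated = popd, radius = radius,
    params = list(nx = nx, ny = ny, radius_factor = radiusFactor))
}

# 8-neighborhood offsets
.nbhd <- cbind(dx = c(-1, -1, -1, 0, 0, 1, 1, 1),
               dy = c(-1, 0, 1, -1, 1, -1, 0, 1))

#' Local maxima (attractor states) of a potential field
#'
#' A populated node is part of a maximum when its potential is at least
#' that of all populated 8-neighbors and strictly above at least one
#' bordering node. A connected plateau of equal potential counts as a
#' single maximum (represented by its lowest-index node) when every
#' populated node bordering the plateau is strictly lower; constant
#' patches therefore contain no maxima.
#'
#' @param field a \linkS4class{PotentialField}.
#' @return a data.frame with columns \code{ix}, \code{iy}, \code{x},
#'   \code{y}, \code{potential}, sorted by decreasing potential.
#' @export
findLocalMaxima <- function(field) {
  pot <- field@potential; popd <- field@populated
  nx <- nrow(pot); ny <- ncol(pot)
  if (!any(popd)) atlasStop("maxima", "field has no populated node")
  # potential equality up to interpolation round-off, so numerically flat
  # regions form one plateau instead of fragmenting into spurious maxima
  eps <- 1e-9 * max(abs(pot[popd]), 1)
  # partition populated nodes into equal-potential plateaus (8-connected);
  # a plateau is one maximum iff it has at least one populated bordering
  # node and all of them are strictly lower
  visited <- matrix(FALSE, nx, ny)
  out <- list()
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (!popd[i, j] || visited[i, j]) next
    level <- pot[i, j]
    queue <- list(c(i, j)); visited[i, j] <- TRUE
    nodes <- list(); hasBorder <- FALSE; allBelow <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      nodes[[length(nodes) + 1]] <- cur
      for (b in seq_len(nrow(.nbhd))) {
        ii <- cur[1] + .nbhd[b, 1]; jj <- cur[2] + .nbhd[b, 2]
        if (ii < 1 || ii > nx || jj < 1 || jj > ny || !popd[ii, jj]) next
        if (abs(pot[ii, jj] - level) <= eps) {
          if (!visited[ii, jj]) {
            visited[ii, jj] <- TRUE
            queue[[length(queue) + 1]] <- c(ii, jj)
          }
        } else {
          hasBorder <- TRUE
          if (pot[ii, jj] > level + eps) allBelow <- FALSE
        }
      }
    }
    if (hasBorder && allBelow) {
      idx <- vapply(nodes, function(nd) (nd[2] - 1L) * nx + nd[1],
                    numeric(1))
      rep <- nodes[[which.min(idx)]]
      out[[length(out) + 1]] <- data.frame(
        ix = rep[1], iy = rep[2], x = field@x[rep[1]],
        y = field@y[rep[2]], potential = level)
    }
  }
  if (!length(out))
    return(data.frame(ix = integer(0), iy = integer(0), x = numeric(0),
                      y = numeric(0), potential = numeric(0)))
  res <- do.call(rbind, out)
  res[order(-res$potential, res$ix, res$iy), , drop = FALSE]
}

#' Gradient vector field of the potential
#'
#' Finite-difference 2-D gradient at every populated node: central
#' differences where both axis neighbors are populated, one-sided where
#' only one is, zero (flagged undefined on that axis) where neither is.
#' Vectors point toward increasing pseudotime.
#'
#' @param field a \linkS4class{PotentialField}.
#' @return a data.frame with one row per populated node: \code{ix},
#'   \code{iy}, \code{x}, \code{y}, \code{gx}, \code{gy},
#'   \code{defined_x}, \code{defined_y}.
#' @export
gradientField <- function(field) {
  pot <- field@potential; popd <- field@populated
  nx <- nrow(pot); ny <- ncol(pot)
  hx <- if (nx > 1) field@x[2] - field@x[1] else 1
  hy <- if (ny > 1) field@y[2] - field@y[1] else 1
  axisDeriv <- function(i, j, axis, h) {
    lo <- c(i, j); hi <- c(i, j)
    lo[axis] <- lo[axis] - 1L; hi[axis] <- hi[axis] + 1L
    okLo <- lo[axis] >= 1 && popd[lo[1], lo[2]]
    okHi <- hi[axis] <= (if (axis == 1) nx else ny) && popd[hi[1], hi[2]]
    if (okLo && okHi)
      c((pot[hi[1], hi[2]] - pot[lo[1], lo[2]]) / (2 * h), TRUE)
    else if (okHi) c((pot[hi[1], hi[2]] - pot[i, j]) / h, TRUE)
    else if (okLo) c((pot[i, j] - pot[lo[1], lo[2]]) / h, TRUE)
    else c(0, FALSE)
  }
  idx <- which(popd, arr.ind = TRUE)
  rows <- lapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]
    dx <- axisDeriv(i, j, 1L, hx)
    dy <- axisDeriv(i, j, 2L, hy)
    data.frame(ix = i, iy = j, x = field@x[i], y = field@y[j],
               gx = dx[1], gy = dy[1],
               defined_x = as.logical(dx[2]), defined_y = as.logical(dy[2]))
  })
  do.call(rbind, rows)
}
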