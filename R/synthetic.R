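#' Default population-by-timepoint composition of the synthetic atlas
#'
#' Frequencies of the fifteen immune populations at the four perinatal
#' stages, following the developmental narrative of the lung immune
#' compartment: Mac I dominates before birth (80\% of macrophage/monocyte
#' cells at E18.5) and collapses after birth, Mac II peaks transiently at
#' P1, Mac III and Mac V rise steadily, Mac IV stays roughly constant, and
#' lymphocytes (B, T, NK, ILC2) expand to dominate by P21. Every population
#' keeps a 2\% floor at every stage so that its marker genes remain
#' observable in each mouse.
#'
#' @return a 15 x 4 matrix of frequencies; columns (timepoints) sum to 1.
#' @export
defaultComposition <- function() {
  tp <- c("E18.5", "P1", "P7", "P21")
  pops <- c("Mac I", "Mac II", "Mac III", "Mac IV", "Mac V",
            "cDC1", "cDC2", "mig-DC", "Mast", "Basophil", "Neutrophil",
            "B", "T", "NK", "ILC2")
  m <- matrix(c(
    # E18.5   P1     P7     P21
    0.52,  0.10,  0.02,  0.02,   # Mac I
    0.04,  0.16,  0.10,  0.02,   # Mac II
    0.02,  0.06,  0.12,  0.10,   # Mac III
    0.04,  0.08,  0.08,  0.07,   # Mac IV
    0.03,  0.12,  0.14,  0.13,   # Mac V
    0.02,  0.03,  0.04,  0.04,   # cDC1
    0.02,  0.04,  0.05,  0.05,   # cDC2
    0.02,  0.02,  0.02,  0.02,   # mig-DC
    0.02,  0.02,  0.02,  0.02,   # Mast
    0.02,  0.02,  0.02,  0.02,   # Basophil
    0.05,  0.06,  0.05,  0.04,   # Neutrophil
    0.03,  0.10,  0.12,  0.18,   # B
    0.08,  0.10,  0.12,  0.20,   # T
    0.05,  0.05,  0.06,  0.06,   # NK
    0.04,  0.04,  0.04,  0.03),  # ILC2
    nrow = length(pops), ncol = length(tp), byrow = TRUE,
    dimnames = list(pops, tp))
  stopifnot(all(abs(colSums(m) - 1) < 1e-9))
  m
}

#' Construct a synthetic atlas design
#'
#' Builds a validated \linkS4class{AtlasDesign}. The defaults emulate the
#' study design of the perinatal mouse lung immune atlas: 8 mice (1 female
#' and 1 male at each of E18.5, P1, P7, P21), 250 cells per mouse, 15
#' immune populations of which Mac I-V share a \code{Cd68} marker,
#' 20 disjoint marker genes per population, Smart-seq2-scale log-normal
#' library sizes, negative-binomial counts, a latent developmental gradient
#' inside Mac V, doublets carrying a non-immune contaminant program
#' (\code{Epcam}/\code{Cdh5}/\code{Col6a2} analogues), and low-depth cells
#' below the read QC threshold.
#'
#' @param nPopulations number of populations; if not 15, generic names
#'   \code{Pop01}, ... are used and macrophage populations are the first
#'   \code{min(5, nPopulations - 1)}.
#' @param markersPerPopulation marker genes per population (default 20).
#' @param nGenes genes simulated (default 2000).
#' @param cellsPerMouse cells per mouse (default 250).
#' @param micePerTimepoint mice per stage (default 2: one female, one male).
#' @param composition population x timepoint frequency matrix; defaults to
#'   \code{\link{defaultComposition}} (or uniform for non-default
#'   population counts).
#' @param gradientPopulation population carrying the latent-time program
#'   (default \code{"Mac V"}; \code{NA} disables the gradient).
#' @param nGradientGenes genes in the gradient program (default 12; half
#'   "early", half "late").
#' @param mouseEffectSd sd of log-normal per-mouse per-gene shifts
#'   (default 0: replicates differ only by sampling noise).
#' @param doubletFraction fraction of cells simulated as doublets
#'   (default 0.05).
#' @param lowdepthFraction fraction of low-depth failed cells
#'   (default 0.05).
#' @param baseDispersion negative-binomial dispersion (default 0.1).
#' @param libMedian median library size of good cells (default 3e5 read
#'   pairs, Smart-seq2 scale).
#' @param libSdLog sd of log library size (default 0.4).
#' @param markerWeight relative weight of a marker inside its population
#'   (default 3; background gene weights are log-normal with median 1).
#' @param markerFold marker elevation inside vs outside its population
#'   (default 1500, i.e. markers are essentially off elsewhere; must be
#'   at least 8).
#' @param prolifFractions named per-timepoint fraction of m/m cells
#'   carrying the proliferation program (defaults 0.6, 0.4, 0.2, 0.1 for
#'   E18.5, P1, P7, P21).
#' @param seed integer seed fully determining the generated atlas.
#' @return an \code{AtlasDesign}.
#' @export
atlasDesign <- function(nPopulations = 15L,
                        markersPerPopulation = 20L,
                        nGenes = 2000L,
                        cellsPerMouse = 250L,
                        micePerTimepoint = 2L,
                        composition = NULL,
                        gradientPopulation = "Mac V",
                        nGradientGenes = 12L,
                        mouseEffectSd = 0,
                        doubletFraction = 0.05,
                        lowdepthFraction = 0.05,
                        baseDispersion = 0.1,
                        libMedian = 3e5,
                        libSdLog = 0.4,
                        markerWeight = 3,
                        markerFold = 1500,
                        prolifFractions = c("E18.5" = 0.6, "P1" = 0.4,
                                            "P7" = 0.2, "P21" = 0.1),
                        seed = 0L) {
  tp <- c("E18.5", "P1", "P7", "P21")
  if (nPopulations == 15L) {
    pops <- rownames(defaultComposition())
    macs <- pops[1:5]
  } else {
    pops <- sprintf("Pop%02d", seq_len(nPopulations))
    macs <- pops[seq_len(min(5L, nPopulations - 1L))]
    if (identical(gradientPopulation, "Mac V"))
      gradientPopulation <- NA_character_
  }
  if (is.null(composition)) {
    composition <- if (nPopulations == 15L) defaultComposition() else
      matrix(1 / nPopulations, nPopulations, length(tp),
             dimnames = list(pops, tp))
  }
  methods::new("AtlasDesign",
    populationNames = pops,
    macrophagePopulations = macs,
    markersPerPopulation = as.integer(markersPerPopulation),
    nGenes = as.integer(nGenes),
    cellsPerMouse = as.integer(cellsPerMouse),
    micePerTimepoint = as.integer(micePerTimepoint),
    timepoints = tp,
    composition = composition,
    gradientPopulation = as.character(gradientPopulation),
    nGradientGenes = as.integer(nGradientGenes),
    mouseEffectSd = mouseEffectSd,
    doubletFraction = doubletFraction,
    lowdepthFraction = lowdepthFraction,
    baseDispersion = baseDispersion,
    libMedian = libMedian,
    libSdLog = libSdLog,
    markerWeight = markerWeight,
    markerFold = markerFold,
    prolifFractions = prolifFractions[tp],
    seed = as.integer(seed))
}

# Gene inventory for a design: symbols and roles (marker_of annotation).
buildGeneInventory <- function(design) {
  pops <- design@populationNames
  mk <- design@markersPerPopulation
  canonical <- c("Mac I" = "Gal", "Mac II" = "Itgax", "Mac III" = "Car4",
                 "Mac IV" = "C1qa", "Mac V" = "Plac8", "cDC1" = "Itgae",
                 "cDC2" = "Cd209a", "mig-DC" = "Mreg", "Mast" = "Mcpt4",
                 "Basophil" = "Mcpt8", "Neutrophil" = "Retnlg",
                 "B" = "Ms4a1", "T" = "Cd3e", "NK" = "Gzma",
                 "ILC2" = "Areg")
  symbols <- character(0); role <- character(0)
  for (p in pops) {
    tag <- gsub("[^A-Za-z0-9]", "", p)
    ms <- sprintf("%s.m%02d", tag, seq_len(mk))
    if (p %in% names(canonical)) ms[1] <- canonical[[p]]
    if (p == "Mast" && mk >= 2) ms[2] <- "Tpsb2"
    symbols <- c(symbols, ms)
    role <- c(role, rep(p, mk))
  }
  special <- c(Cd68 = "macrophage_shared", Ptprc = "immune_pan",
               Mki67 = "proliferation", Mcm5 = "proliferation")
  contam <- c("Epcam", "Cdh5", "Col6a2")
  nContam <- 15L
  if (nContam > 3)
    contam <- c(contam, sprintf("Contam.g%02d", seq_len(nContam - 3L)))
  nGrad <- if (is.na(design@gradientPopulation)) 0L else design@nGradientGenes
  grad <- character(0); gradRole <- character(0)
  if (nGrad > 0) {
    nEarly <- ceiling(nGrad / 2)
    grad <- c(sprintf("Grad.e%02d", seq_len(nEarly)),
              sprintf("Grad.l%02d", seq_len(nGrad - nEarly)))
    gradRole <- c(rep("gradient_early", nEarly),
                  rep("gradient_late", nGrad - nEarly))
  }
  symbols <- c(symbols, names(special), contam, grad)
  role <- c(role, unname(special), rep("contaminant", length(contam)),
            gradRole)
  nBack <- design@nGenes - length(symbols)
  if (nBack < 0)
    atlasStop("generate_atlas",
              "infeasible design: structured genes exceed nGenes")
  symbols <- c(symbols, sprintf("Gene%04d", seq_len(nBack)))
  role <- c(role, rep("background", nBack))
  data.frame(gene_symbol = symbols, marker_of = role,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic perinatal lung immune atlas
#'
#' Draws a cell x gene count matrix from a gamma-Poisson (negative
#' binomial) model under an \linkS4class{AtlasDesign}: cell \eqn{i} of
#' population \eqn{p} has expected counts
#' \eqn{\mu_{ig} = \ell_i \, w_{pg} / \sum_g w_{pg}} with log-normal
#' library sizes \eqn{\ell_i}, population profiles \eqn{w_p} in which the
#' population's marker genes are elevated \code{markerFold}-fold, log-normal
#' per-mouse per-gene shifts of sd \code{mouseEffectSd}, gradient-population
#' cells interpolating an early and a late program by their latent time,
#' doublets summing the draws of two random parent populations plus a
#' non-immune contaminant block, and low-depth cells with library sizes
#' below the read QC threshold.
#'
#' The generated truth is embedded Bioconductor-style: \code{colData}
#' columns \code{true_population} (with \code{"doublet"} for doublets),
#' \code{latent_time}, \code{is_doublet}, \code{is_lowdepth},
#' \code{is_proliferative}; \code{rowData} column \code{marker_of};
#' \code{metadata} entries \code{design} and \code{mouse_effects}.
#'
#' @param design an \code{AtlasDesign}; its \code{seed} slot fully
#'   determines the output.
#' @return a \link[SingleCellExperiment]{SingleCellExperiment} with a
#'   sparse integer \code{counts} assay (genes x cells) and the truth
#'   annotations above.
#' @examples
#' sce <- generateAtlas(atlasDesign(cellsPerMouse = 20L, nGenes = 300L,
#'                                  markersPerPopulation = 5L))
#' table(sce$true_population)
#' @export
generateAtlas <- function(design) {
  methods::validObject(design)
  withSeed(design@seed, {
    inv <- buildGeneInventory(design)
    nG <- design@nGenes
    pops <- design@populationNames
    macs <- design@macrophagePopulations
    tps <- design@timepoints
    off <- design@markerWeight / design@markerFold

    background <- rlnorm(nG, meanlog = 0, sdlog = 1.5)
    # population weight profiles (genes x populations)
    W <- matrix(rep(background, length(pops)), nG, length(pops),
                dimnames = list(inv$gene_symbol, pops))
    isMarker <- inv$marker_of %in% pops
    W[isMarker, ] <- off
    for (p in pops)
      W[inv$marker_of == p, p] <- design@markerWeight
    W[inv$marker_of == "macrophage_shared", ] <- off
    W[inv$marker_of == "macrophage_shared", macs] <- design@markerWeight
    W[inv$marker_of == "immune_pan", ] <- 2
    # non-immune lineage genes are essentially silent in immune cells
    W[inv$marker_of == "contaminant", ] <- off / 10
    W[inv$marker_of == "proliferation", ] <- 0
    gradEarly <- inv$marker_of == "gradient_early"
    gradLate <- inv$marker_of == "gradient_late"
    W[gradEarly | gradLate, ] <- off
    gradientWeight <- 1.5

    contamW <- numeric(nG)
    contamW[inv$marker_of == "contaminant"] <- 5

    nMice <- length(tps) * design@micePerTimepoint
    sexes <- rep(c("female", "male"), length.out = design@micePerTimepoint)
    mouseTab <- data.frame(
      mouse_id = sprintf("m_%s_%s", rep(tps, each = design@micePerTimepoint),
                         rep(substr(sexes, 1, 1), length(tps))),
      timepoint = rep(tps, each = design@micePerTimepoint),
      sex = rep(sexes, length(tps)), stringsAsFactors = FALSE)
    mouseEffects <- matrix(1, nG, nMice,
                           dimnames = list(inv$gene_symbol,
                                           mouseTab$mouse_id))
    if (design@mouseEffectSd > 0)
      mouseEffects[] <- exp(matrix(rnorm(nG * nMice, 0,
                                         design@mouseEffectSd), nG, nMice))

    nCells <- nMice * design@cellsPerMouse
    size <- 1 / design@baseDispersion
    counts <- matrix(0, nG, nCells)
    cellMouse <- rep(mouseTab$mouse_id, each = design@cellsPerMouse)
    cellTp <- rep(mouseTab$timepoint, each = design@cellsPerMouse)
    cellSex <- rep(mouseTab$sex, each = design@cellsPerMouse)
    truePop <- character(nCells)
    latent <- rep(NA_real_, nCells)
    isDoublet <- logical(nCells)
    isLow <- logical(nCells)
    isProlif <- logical(nCells)
    tpIndex <- match(cellTp, tps)

    roles <- matrix(runif(nCells * 2), nCells, 2)
    for (i in seq_len(nCells)) {
      mi <- match(cellMouse[i], mouseTab$mouse_id)
      Wm <- W * mouseEffects[, mi]
      isLow[i] <- roles[i, 1] < design@lowdepthFraction
      isDoublet[i] <- !isLow[i] &&
        roles[i, 1] < design@lowdepthFraction + design@doubletFraction
      lib <- if (isLow[i]) runif(1, 5000, 45000) else
        rlnorm(1, meanlog = log(design@libMedian), sdlog = design@libSdLog)
      comp <- design@composition[, cellTp[i]]
      if (isDoublet[i]) {
        truePop[i] <- "doublet"
        parents <- sample(pops, 2, replace = FALSE, prob = comp)
        w1 <- Wm[, parents[1]]; w2 <- Wm[, parents[2]]
        mu <- (lib / 2) * (w1 / sum(w1) + w2 / sum(w2)) +
          (0.05 * lib) * contamW / sum(contamW)
        counts[, i] <- rnbinom(nG, mu = mu, size = size)
        next
      }
      p <- sample(pops, 1, prob = comp)
      truePop[i] <- p
      w <- Wm[, p]
      if (!is.na(design@gradientPopulation) &&
          p == design@gradientPopulation) {
        # latent maturation is drawn uniformly in every mouse so the full
        # program range is observable within each replicate
        t <- runif(1)
        latent[i] <- t
        # the program ramps between a floor and a high level so gradient
        # genes stay detectable in the population at every stage
        gradFloor <- 0.1
        w[gradEarly] <- (gradientWeight * (1 - t) + gradFloor * t) *
          mouseEffects[gradEarly, mi]
        w[gradLate] <- (gradFloor * (1 - t) + gradientWeight * t) *
          mouseEffects[gradLate, mi]
      }
      if (p %in% macs &&
          runif(1) < design@prolifFractions[[cellTp[i]]]) {
        isProlif[i] <- TRUE
        # moderate amplitude: reliably detected (mean count >> 0) without
        # dominating the within-population geometry
        w[inv$marker_of == "proliferation"] <-
          0.4 * mouseEffects[inv$marker_of == "proliferation", mi]
      }
      mu <- lib * w / sum(w)
      counts[, i] <- rnbinom(nG, mu = mu, size = size)
    }

    cellIds <- sprintf("cell%04d", seq_len(nCells))
    m <- Matrix::Matrix(counts, sparse = TRUE)
    dimnames(m) <- list(inv$gene_symbol, cellIds)
    cd <- S4Vectors::DataFrame(
      cell_id = cellIds,
      mouse_id = cellMouse,
      sex = cellSex,
      timepoint = cellTp,
      mapped_reads = as.integer(Matrix::colSums(m)),
      n_genes = as.integer(Matrix::colSums(m > 0)),
      true_population = truePop,
      latent_time = latent,
      is_doublet = isDoublet,
      is_lowdepth = isLow,
      is_proliferative = isProlif,
      row.names = cellIds)
    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = m),
      colData = cd,
      rowData = S4Vectors::DataFrame(inv, row.names = inv$gene_symbol))
    S4Vectors::metadata(sce)$design <- design
    S4Vectors::metadata(sce)$mouse_effects <- mouseEffects
    sce
  })
}

#' Generate a synthetic B-cell germline-identity table
#'
#' Per-cell V- and J-segment germline identity fractions under a per-site
#' mutation model: each cell's V segment (effective length \code{vLength})
#' and J segment (\code{jLength}) accumulate binomially distributed
#' somatic mutations at rate \code{shmRate}; identity is the unmutated
#' fraction. With \code{shmRate = 0} all identities are exactly 1.
#'
#' @param nCells number of cells (rows).
#' @param shmRate per-site somatic hypermutation rate in [0, 1].
#' @param seed integer seed.
#' @param vLength,jLength effective segment lengths in nucleotides
#'   (defaults 300 and 50).
#' @return a data.frame with columns \code{cell_id}, \code{v_identity},
#'   \code{j_identity}, \code{chain}.
#' @export
generateGermlineTable <- function(nCells, shmRate, seed = 0L,
                                  vLength = 300L, jLength = 50L) {
  if (nCells < 1) atlasStop("generate_germline", "nCells must be >= 1")
  if (shmRate < 0 || shmRate > 1)
    atlasStop("generate_germline", "shmRate must be in [0, 1]")
  withSeed(seed, {
    data.frame(
      cell_id = sprintf("bcell%04d", seq_len(nCells)),
      v_identity = 1 - rbinom(nCells, vLength, shmRate) / vLength,
      j_identity = 1 - rbinom(nCells, jLength, shmRate) / jLength,
      chain = sample(c("IGH", "IGK", "IGL"), nCells, replace = TRUE),
      stringsAsFactors = FALSE)
  })
}
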