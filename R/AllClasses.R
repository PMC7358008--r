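#' @import methods
#' @importFrom stats var median quantile rnorm runif rbinom rnbinom rlnorm
#'   setNames prcomp dist cor complete.cases
#' @importFrom utils head read.delim write.table
NULL

#' Design of a synthetic perinatal lung immune atlas
#'
#' An \code{AtlasDesign} captures the study design the generator emulates:
#' eight mice (two per timepoint across E18.5, P1, P7 and P21), around
#' fifteen immune populations of which five are macrophage/monocyte ("m/m")
#' populations sharing a Cd68-like marker, per-population marker programs,
#' an optional population carrying a latent developmental gradient,
#' per-mouse expression shifts, doublets carrying a non-immune contaminant
#' program, and low-depth failed cells.
#'
#' @slot populationNames character vector of population labels.
#' @slot macrophagePopulations subset of \code{populationNames} forming the
#'   m/m compartment (share the \code{Cd68} marker).
#' @slot markersPerPopulation integer, marker genes per population.
#' @slot nGenes total number of genes simulated.
#' @slot cellsPerMouse integer, cells sequenced per mouse.
#' @slot micePerTimepoint integer, mice per developmental stage.
#' @slot timepoints character, ordered developmental stages.
#' @slot composition populations x timepoints matrix of population
#'   frequencies; each column sums to 1.
#' @slot gradientPopulation population whose cells carry a latent time in
#'   [0,1] driving a monotone expression program, or \code{NA_character_}.
#' @slot nGradientGenes integer, genes in the gradient program.
#' @slot mouseEffectSd non-negative real; sd of log-normal per-mouse,
#'   per-gene expression shifts.
#' @slot doubletFraction fraction of cells simulated as doublets.
#' @slot lowdepthFraction fraction of cells simulated with library size
#'   below the read QC threshold.
#' @slot baseDispersion negative-binomial dispersion (1/size).
#' @slot libMedian median library size (read pairs) of good cells.
#' @slot libSdLog sd of log library size.
#' @slot markerWeight relative expression weight of a marker gene inside
#'   its population (background genes have log-normal weights with median 1).
#' @slot markerFold fold elevation of a marker inside vs outside its
#'   population (must be >= 8).
#' @slot prolifFractions named fraction of m/m cells per timepoint carrying
#'   the proliferation program (Mki67/Mcm5 analogues).
#' @slot seed integer seed; together with the design it fully determines
#'   the generated data.
#' @export
setClass("AtlasDesign", representation(
  populationNames = "character",
  macrophagePopulations = "character",
  markersPerPopulation = "integer",
  nGenes = "integer",
  cellsPerMouse = "integer",
  micePerTimepoint = "integer",
  timepoints = "character",
  composition = "matrix",
  gradientPopulation = "character",
  nGradientGenes = "integer",
  mouseEffectSd = "numeric",
  doubletFraction = "numeric",
  lowdepthFraction = "numeric",
  baseDispersion = "numeric",
  libMedian = "numeric",
  libSdLog = "numeric",
  markerWeight = "numeric",
  markerFold = "numeric",
  prolifFractions = "numeric",
  seed = "integer"
))

setValidity("AtlasDesign", function(object) {
  msg <- character()
  np <- length(object@populationNames)
  if (np < 2L) msg <- c(msg, "need at least 2 populations")
  if (anyDuplicated(object@populationNames))
    msg <- c(msg, "population names must be unique")
  if (!all(object@macrophagePopulations %in% object@populationNames))
    msg <- c(msg, "macrophagePopulations must be a subset of populationNames")
  if (!identical(dim(object@composition),
                 c(np, length(object@timepoints))))
    msg <- c(msg, "composition must be populations x timepoints")
  if (any(object@composition < 0))
    msg <- c(msg, "composition frequencies must be non-negative")
  if (any(abs(colSums(object@composition) - 1) > 1e-9))
    msg <- c(msg, "composition columns must sum to 1")
  if (object@markersPerPopulation * np >= object@nGenes)
    msg <- c(msg, sprintf(
      "infeasible design: %d marker genes requested but only %d genes",
      object@markersPerPopulation * np, object@nGenes))
  if (!is.na(object@gradientPopulation) &&
      !object@gradientPopulation %in% object@populationNames)
    msg <- c(msg, "gradientPopulation must name a population")
  if (object@mouseEffectSd < 0) msg <- c(msg, "mouseEffectSd must be >= 0")
  if (object@doubletFraction < 0 || object@doubletFraction >= 1)
    msg <- c(msg, "doubletFraction must be in [0, 1)")
  if (object@lowdepthFraction < 0 || object@lowdepthFraction >= 1)
    msg <- c(msg, "lowdepthFraction must be in [0, 1)")
  if (object@baseDispersion <= 0) msg <- c(msg, "baseDispersion must be > 0")
  if (object@markerFold < 8)
    msg <- c(msg, "markerFold must be >= 8 (markers elevated at least 8-fold)")
  if (!setequal(names(object@prolifFractions), object@timepoints))
    msg <- c(msg, "prolifFractions must be named by the timepoints")
  if (length(msg)) msg else TRUE
})

#' Cell-level quality-control report
#'
#' Accounts for every input cell across the QC chain: read-depth and
#' gene-detection filters, then cluster-level doublet exclusion. The
#' \code{disposition} vector assigns exactly one outcome to each input cell
#' (\code{"pass"}, \code{"fail_reads"}, \code{"fail_genes"},
#' \code{"fail_both"}, \code{"doublet"}); a cell failing both filters
#' increments both failure counters but is removed once.
#'
#' @slot nInput cells before any filter.
#' @slot nFailReads cells below the read threshold (includes cells also
#'   failing the gene filter).
#' @slot nFailGenes cells below the gene-detection threshold (includes
#'   cells also failing the read filter).
#' @slot nAfterFilters cells surviving both filters.
#' @slot nDoubletsRemoved cells removed with flagged doublet clusters.
#' @slot nFinal cells entering the analysis;
#'   \code{nFinal == nAfterFilters - nDoubletsRemoved}.
#' @slot disposition named character vector, one entry per input cell.
#' @export
setClass("QCReport", representation(
  nInput = "integer", nFailReads = "integer", nFailGenes = "integer",
  nAfterFilters = "integer", nDoubletsRemoved = "integer",
  nFinal = "integer", disposition = "character"
))

setValidity("QCReport", function(object) {
  msg <- character()
  if (object@nFinal != object@nAfterFilters - object@nDoubletsRemoved)
    msg <- c(msg, "nFinal must equal nAfterFilters - nDoubletsRemoved")
  if (object@nDoubletsRemoved > object@nAfterFilters)
    msg <- c(msg, "cannot remove more doublets than filtered cells")
  if (any(c(object@nInput, object@nFailReads, object@nFailGenes,
            object@nAfterFilters, object@nDoubletsRemoved,
            object@nFinal) < 0L))
    msg <- c(msg, "all counts must be non-negative")
  if (length(object@disposition)) {
    if (length(object@disposition) != object@nInput)
      msg <- c(msg, "disposition must cover every input cell")
    ok <- c("pass", "fail_reads", "fail_genes", "fail_both", "doublet")
    if (!all(object@disposition %in% ok))
      msg <- c(msg, "unknown disposition label")
    if (sum(object@disposition %in% c("pass")) != object@nFinal)
      msg <- c(msg, "passing dispositions must equal nFinal")
  }
  if (length(msg)) msg else TRUE
})

#' Per-mouse Fano-factor feature selection result
#'
#' Holds the genes selected as highly variable because they have a high
#' Fano factor (variance/mean of CPM) in most mice, with the per-mouse rank
#' table and the per-gene support (number of mice in which the gene ranks
#' within the high-Fano cutoff).
#'
#' @slot selectedGenes ordered character vector of selected gene symbols.
#' @slot support named integer vector, per gene, of mice where the gene is
#'   high-Fano.
#' @slot rankTable genes x mice matrix of within-mouse Fano ranks
#'   (1 = highest Fano).
#' @slot params list with \code{n_features}, \code{high_rank_cutoff} and
#'   the mouse ids used.
#' @export
setClass("FanoFeatures", representation(
  selectedGenes = "character", support = "integer",
  rankTable = "matrix", params = "list"
))

setValidity("FanoFeatures", function(object) {
  msg <- character()
  if (anyDuplicated(object@selectedGenes))
    msg <- c(msg, "selected genes must be unique")
  if (!all(object@selectedGenes %in% rownames(object@rankTable)))
    msg <- c(msg, "selected genes must appear in the rank table")
  if (length(msg)) msg else TRUE
})

#' Pseudotime interpolated as a scalar potential on a grid
#'
#' A regular lattice over the bounding box of a 2-D embedding. A node is
#' populated when at least one cell lies within \code{radius}; the potential
#' at a populated node is the inverse-distance-weighted mean of the
#' pseudotimes of cells within the radius. Local maxima of the potential
#' mark attractor states; the 2-D gradient gives the vector field.
#'
#' @slot x,y grid node coordinates (lengths nx and ny).
#' @slot potential nx x ny matrix, \code{NA} at unpopulated nodes.
#' @slot populated nx x ny logical matrix.
#' @slot radius the population/interpolation radius actually used.
#' @slot params list recording nx, ny and radius_factor.
#' @export
setClass("PotentialField", representation(
  x = "numeric", y = "numeric", potential = "matrix",
  populated = "matrix", radius = "numeric", params = "list"
))

setValidity("PotentialField", function(object) {
  msg <- character()
  if (!identical(dim(object@potential),
                 c(length(object@x), length(object@y))))
    msg <- c(msg, "potential must be nx x ny")
  if (!identical(dim(object@populated), dim(object@potential)))
    msg <- c(msg, "populated mask must match potential dimensions")
  if (any(is.na(object@potential[object@populated])))
    msg <- c(msg, "populated nodes must carry a potential value")
  if (length(msg)) msg else TRUE
})

#' Result of the same-mouse vs different-mouse pair-distance test
#'
#' For one (cell type, timepoint) stratum: embedded distances of cell pairs
#' drawn within a mouse and across mice, the two-sample KS statistic between
#' the two distance distributions, the one-sided p-value for
#' different-mouse pairs being stochastically longer, and the verdict.
#'
#' @slot cellType,timepoint the stratum.
#' @slot sameDistances,diffDistances sampled pair distances.
#' @slot statistic two-sided KS statistic (sup CDF difference).
#' @slot pValue one-sided p-value (different-mouse distances longer).
#' @slot verdict one of \code{"no_batch_effect"}, \code{"batch_effect"},
#'   \code{"insufficient_cells"}.
#' @export
setClass("PairDistanceResult", representation(
  cellType = "character", timepoint = "character",
  sameDistances = "numeric", diffDistances = "numeric",
  statistic = "numeric", pValue = "numeric", verdict = "character"
))

setValidity("PairDistanceResult", function(object) {
  msg <- character()
  if (!object@verdict %in%
      c("no_batch_effect", "batch_effect", "insufficient_cells"))
    msg <- c(msg, "unknown verdict")
  if (object@verdict != "insufficient_cells") {
    if (object@statistic < 0 || object@statistic > 1)
      msg <- c(msg, "KS statistic must lie in [0, 1]")
    if (object@pValue < 0 || object@pValue > 1)
      msg <- c(msg, "p-value must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "AtlasDesign", function(object) {
  cat("AtlasDesign:", length(object@populationNames), "populations,",
      object@nGenes, "genes,",
      length(object@timepoints) * object@micePerTimepoint, "mice x",
      object@cellsPerMouse, "cells\n")
  cat("  timepoints:", paste(object@timepoints, collapse = ", "), "\n")
  cat("  m/m populations:",
      paste(object@macrophagePopulations, collapse = ", "), "\n")
  cat("  gradient population:", object@gradientPopulation,
      " mouse effect sd:", object@mouseEffectSd, "\n")
  cat("  doublet fraction:", object@doubletFraction,
      " low-depth fraction:", object@lowdepthFraction,
      " seed:", object@seed, "\n")
})

setMethod("show", "QCReport", function(object) {
  cat("QCReport:", object@nInput, "cells in\n")
  cat("  failed read filter: ", object@nFailReads,
      "; failed gene filter: ", object@nFailGenes, "\n", sep = "")
  cat("  after filters:", object@nAfterFilters,
      "- doublets removed:", object@nDoubletsRemoved,
      "-> final:", object@nFinal, "\n")
})

setMethod("show", "FanoFeatures", function(object) {
  cat("FanoFeatures:", length(object@selectedGenes), "genes selected over",
      ncol(object@rankTable), "mice\n")
  cat("  head:", paste(head(object@selectedGenes, 5), collapse = ", "), "\n")
})

setMethod("show", "PotentialField", function(object) {
  cat("PotentialField:", length(object@x), "x", length(object@y),
      "grid;", sum(object@populated), "populated nodes\n")
})

setMethod("show", "PairDistanceResult", function(object) {
  cat("PairDistanceResult [", object@cellType, "/", object@timepoint,
      "]: D =", round(object@statistic, 4),
      "p =", signif(object@pValue, 3), "->", object@verdict, "\n")
})
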