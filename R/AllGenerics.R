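#' Accessors for lungatlas result objects
#'
#' \code{selectedGenes} returns the ordered highly-variable gene list of a
#' \linkS4class{FanoFeatures} object; \code{featureSupport} the per-gene
#' count of mice in which the gene is high-Fano; \code{qcReport} the
#' \linkS4class{QCReport} attached to a filtered experiment;
#' \code{populatedNodes} the logical mask of grid nodes of a
#' \linkS4class{PotentialField} backed by at least one cell.
#'
#' @param x the object.
#' @return the slot content described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("selectedGenes", function(x) standardGeneric("selectedGenes"))

#' @rdname accessors
#' @export
setMethod("selectedGenes", "FanoFeatures", function(x) x@selectedGenes)

#' @rdname accessors
#' @export
setGeneric("featureSupport", function(x) standardGeneric("featureSupport"))

#' @rdname accessors
#' @export
setMethod("featureSupport", "FanoFeatures", function(x) x@support)

#' @rdname accessors
#' @export
setGeneric("qcReport", function(x) standardGeneric("qcReport"))

#' @rdname accessors
#' @export
setMethod("qcReport", "SingleCellExperiment", function(x)
  S4Vectors::metadata(x)$qc_report)

#' @rdname accessors
#' @export
setGeneric("populatedNodes", function(x) standardGeneric("populatedNodes"))

#' @rdname accessors
#' @export
setMethod("populatedNodes", "PotentialField", function(x) x@populated)

#' @rdname accessors
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))

#' @rdname accessors
#' @export
setMethod("verdict", "PairDistanceResult", function(x) x@verdict)
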