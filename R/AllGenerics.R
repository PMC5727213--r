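#' Accessors for aromaBSA classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an aromaBSA S4 object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))
#' @rdname accessors
#' @export
setGeneric("compounds", function(x) standardGeneric("compounds"))
#' @rdname accessors
#' @export
setGeneric("phenoMeans", function(x) standardGeneric("phenoMeans"))
#' @rdname accessors
#' @export
setGeneric("phenoSDs", function(x) standardGeneric("phenoSDs"))
#' @rdname accessors
#' @export
setGeneric("repCounts", function(x) standardGeneric("repCounts"))
#' @rdname accessors
#' @export
setGeneric("highBulk", function(x) standardGeneric("highBulk"))
#' @rdname accessors
#' @export
setGeneric("lowBulk", function(x) standardGeneric("lowBulk"))
#' @rdname accessors
#' @export
setGeneric("bulkRule", function(x) standardGeneric("bulkRule"))
#' @rdname accessors
#' @export
setGeneric("snr", function(x) standardGeneric("snr"))
#' @rdname accessors
#' @export
setGeneric("bulkLabels", function(x) standardGeneric("bulkLabels"))
#' @rdname accessors
#' @export
setGeneric("bioRep", function(x) standardGeneric("bioRep"))
#' @rdname accessors
#' @export
setGeneric("techRep", function(x) standardGeneric("techRep"))
#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
#' @rdname accessors
#' @export
setGeneric("wilksTrace", function(x) standardGeneric("wilksTrace"))
#' @rdname accessors
#' @export
setGeneric("isEmptyModel", function(x) standardGeneric("isEmptyModel"))
#' @rdname accessors
#' @export
setGeneric("markerIntersection", function(x) standardGeneric("markerIntersection"))
#' @rdname accessors
#' @export
setGeneric("vennRegions", function(x) standardGeneric("vennRegions"))
#' @rdname accessors
#' @export
setGeneric("originalPct", function(x) standardGeneric("originalPct"))
#' @rdname accessors
#' @export
setGeneric("cvPct", function(x) standardGeneric("cvPct"))
#' @rdname accessors
#' @export
setGeneric("holdoutPct", function(x) standardGeneric("holdoutPct"))

#' @rdname accessors
#' @export
setMethod("individuals", "PhenotypeTable", function(x) rownames(x@means))
#' @rdname accessors
#' @export
setMethod("compounds", "PhenotypeTable", function(x) colnames(x@means))
#' @rdname accessors
#' @export
setMethod("phenoMeans", "PhenotypeTable", function(x) x@means)
#' @rdname accessors
#' @export
setMethod("phenoSDs", "PhenotypeTable", function(x) x@sds)
#' @rdname accessors
#' @export
setMethod("repCounts", "PhenotypeTable", function(x) x@nreps)

#' @rdname accessors
#' @export
setMethod("compounds", "BulkDesign", function(x) x@compound)
#' @rdname accessors
#' @export
setMethod("highBulk", "BulkDesign", function(x) x@high)
#' @rdname accessors
#' @export
setMethod("lowBulk", "BulkDesign", function(x) x@low)
#' @rdname accessors
#' @export
setMethod("bulkRule", "BulkDesign", function(x) x@rule)

#' @rdname accessors
#' @export
setMethod("snr", "SignalMatrix", function(x) SummarizedExperiment::assay(x, "snr"))
#' @rdname accessors
#' @export
setMethod("bulkLabels", "SignalMatrix", function(x) SummarizedExperiment::colData(x)$bulk)
#' @rdname accessors
#' @export
setMethod("bioRep", "SignalMatrix", function(x) SummarizedExperiment::colData(x)$bioRep)
#' @rdname accessors
#' @export
setMethod("techRep", "SignalMatrix", function(x) SummarizedExperiment::colData(x)$techRep)

#' @rdname accessors
#' @export
setMethod("selectedFeatures", "DfaModel", function(x) x@features)
#' @rdname accessors
#' @export
setMethod("wilksTrace", "DfaModel", function(x) x@lambdaTrace)
#' @rdname accessors
#' @export
setMethod("isEmptyModel", "DfaModel", function(x) x@noDiscriminators)

#' @rdname accessors
#' @export
setMethod("markerIntersection", "MarkerSelection", function(x) x@intersection)
#' @rdname accessors
#' @export
setMethod("vennRegions", "MarkerSelection", function(x) x@regions)

#' @rdname accessors
#' @export
setMethod("originalPct", "ClassificationReport", function(x) x@originalPct)
#' @rdname accessors
#' @export
setMethod("cvPct", "ClassificationReport", function(x) x@cvPct)
#' @rdname accessors
#' @export
setMethod("holdoutPct", "ClassificationReport", function(x) x@holdoutPct)
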