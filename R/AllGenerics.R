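#' Accessors for package classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object of one of the package classes.
#' @param ... passed to methods.
#' @return The corresponding component (see methods).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("boldData", function(x) standardGeneric("boldData"))
#' @rdname accessors
#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))
#' @rdname accessors
#' @export
setGeneric("voxelAffine", function(x) standardGeneric("voxelAffine"))
#' @rdname accessors
#' @export
setGeneric("motionParams", function(x) standardGeneric("motionParams"))
#' @rdname accessors
#' @export
setGeneric("scaleNames", function(x) standardGeneric("scaleNames"))
#' @rdname accessors
#' @export
setGeneric("scaleLabels", function(x, scale) standardGeneric("scaleLabels"))
#' @rdname accessors
#' @export
setGeneric("regionTable", function(x, scale) standardGeneric("regionTable"))
#' @rdname accessors
#' @export
setGeneric("mergeMap", function(x, from, to) standardGeneric("mergeMap"))
#' @rdname accessors
#' @export
setGeneric("brainMask", function(x) standardGeneric("brainMask"))
#' @rdname accessors
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @rdname accessors
#' @export
setGeneric("isZStandardised", function(x) standardGeneric("isZStandardised"))
#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))
#' @rdname accessors
#' @export
setGeneric("probeExpr", function(x) standardGeneric("probeExpr"))
#' @rdname accessors
#' @export
setGeneric("probeTable", function(x) standardGeneric("probeTable"))
#' @rdname accessors
#' @export
setGeneric("probeCalls", function(x) standardGeneric("probeCalls"))
#' @rdname accessors
#' @export
setGeneric("rnaseqExpr", function(x) standardGeneric("rnaseqExpr"))
#' @rdname accessors
#' @export
setGeneric("sampleAnnotation", function(x) standardGeneric("sampleAnnotation"))

#' @rdname accessors
#' @export
setMethod("subjectId", "BoldRun", function(x) x@subjectId)
#' @rdname accessors
#' @export
setMethod("subjectId", "MotionTrace", function(x) x@subjectId)
#' @rdname accessors
#' @export
setMethod("boldData", "BoldRun", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("trSeconds", "BoldRun", function(x) x@trSeconds)
#' @rdname accessors
#' @export
setMethod("voxelAffine", "BoldRun", function(x) x@affine)
#' @rdname accessors
#' @export
setMethod("voxelAffine", "HierarchicalParcellation", function(x) x@affine)
#' @rdname accessors
#' @export
setMethod("voxelAffine", "ReHoMap", function(x) x@affine)
#' @rdname accessors
#' @export
setMethod("motionParams", "MotionTrace", function(x) x@params)
#' @rdname accessors
#' @export
setMethod("scaleNames", "HierarchicalParcellation", function(x) names(x@labels))

#' @rdname accessors
#' @export
setMethod("scaleLabels", "HierarchicalParcellation", function(x, scale) {
  if (!scale %in% names(x@labels))
    stop("unknown scale '", scale, "'; available: ",
         paste(names(x@labels), collapse = ", "))
  x@labels[[scale]]
})

#' @rdname accessors
#' @export
setMethod("regionTable", "HierarchicalParcellation", function(x, scale) {
  if (!scale %in% names(x@regions))
    stop("unknown scale '", scale, "'")
  x@regions[[scale]]
})

#' @rdname accessors
#' @export
setMethod("mergeMap", "HierarchicalParcellation", function(x, from, to) {
  key <- paste0(from, "->", to)
  if (!key %in% names(x@mergeMaps))
    stop("no merge map from '", from, "' to '", to, "'")
  x@mergeMaps[[key]]
})

#' @rdname accessors
#' @export
setMethod("brainMask", "HierarchicalParcellation", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("brainMask", "ReHoMap", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("mapValues", "ReHoMap", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("isZStandardised", "ReHoMap", function(x) x@zStandardised)
#' @rdname accessors
#' @export
setMethod("featureMatrix", "FeatureDataset", function(x) x@features)
#' @rdname accessors
#' @export
setMethod("groupLabels", "FeatureDataset", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("subjectId", "FeatureDataset", function(x) x@subjectIds)
#' @rdname accessors
#' @export
setMethod("probeExpr", "ProbeBundle", function(x) x@expr)
#' @rdname accessors
#' @export
setMethod("probeTable", "ProbeBundle", function(x) x@probes)
#' @rdname accessors
#' @export
setMethod("probeCalls", "ProbeBundle", function(x) x@calls)
#' @rdname accessors
#' @export
setMethod("rnaseqExpr", "ProbeBundle", function(x) x@rnaseq)
#' @rdname accessors
#' @export
setMethod("sampleAnnotation", "ProbeBundle", function(x) x@samples)
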