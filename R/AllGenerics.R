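#' Accessors for package classes
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprs", function(object) standardGeneric("exprs"))

#' @rdname accessors
#' @export
setGeneric("drugResponse", function(object) standardGeneric("drugResponse"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("responseValues",
           function(object) standardGeneric("responseValues"))

#' @rdname accessors
#' @export
setGeneric("responseOrientation",
           function(object) standardGeneric("responseOrientation"))

#' @rdname accessors
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))

#' @rdname accessors
#' @export
setGeneric("zscores", function(object) standardGeneric("zscores"))

#' @rdname accessors
#' @export
setGeneric("rankedGenes", function(object) standardGeneric("rankedGenes"))

#' @rdname accessors
#' @export
setGeneric("rankingScores",
           function(object) standardGeneric("rankingScores"))

#' @rdname accessors
#' @export
setGeneric("rankingMethod",
           function(object) standardGeneric("rankingMethod"))

#' @rdname accessors
#' @export
setGeneric("informativeGenes",
           function(object) standardGeneric("informativeGenes"))

#' @rdname accessors
#' @export
setGeneric("geneWeights", function(object) standardGeneric("geneWeights"))

#' @rdname accessors
#' @export
setGeneric("featureIds", function(object) standardGeneric("featureIds"))

#' @rdname accessors
#' @export
setGeneric("gridTable", function(object) standardGeneric("gridTable"))

#' @rdname accessors
#' @export
setGeneric("bestModelSpec", function(object) standardGeneric("bestModelSpec"))

#' @rdname accessors
#' @export
setGeneric("bestAccuracy", function(object) standardGeneric("bestAccuracy"))

#' @rdname accessors
#' @export
setGeneric("accuracyProfile",
           function(object) standardGeneric("accuracyProfile"))

#' @rdname accessors
#' @export
setGeneric("transferAccuracy",
           function(object) standardGeneric("transferAccuracy"))

#' @rdname accessors
#' @export
setGeneric("transferAuc", function(object) standardGeneric("transferAuc"))

#' @rdname accessors
#' @export
setGeneric("perSampleTable", function(object) standardGeneric("perSampleTable"))

#' @rdname accessors
#' @export
setGeneric("overlapCounts", function(object) standardGeneric("overlapCounts"))
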