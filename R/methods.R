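# Accessor methods and show() methods.

#' @rdname accessors
#' @export
setMethod("exprs", "DrugScreen", function(object)
    SummarizedExperiment::assay(object, "exprs"))

#' @rdname accessors
#' @export
setMethod("drugResponse", "DrugScreen", function(object) {
    cd <- SummarizedExperiment::colData(object)
    if (!"response" %in% colnames(cd))
        stop("cohort carries no response column")
    ori <- S4Vectors::metadata(object)$orientation
    if (is.null(ori))
        stop("cohort carries no response orientation")
    DrugResponse(sampleIds = colnames(object), values = cd$response,
                 orientation = ori)
})

#' @rdname accessors
#' @export
setMethod("groundTruth", "DrugScreen", function(object)
    S4Vectors::metadata(object)$groundTruth)

#' @rdname accessors
#' @export
setMethod("sampleIds", "DrugResponse", function(object) object@sampleIds)

#' @rdname accessors
#' @export
setMethod("sampleIds", "SampleLabels", function(object) object@sampleIds)

#' @rdname accessors
#' @export
setMethod("responseValues", "DrugResponse", function(object) {
    v <- object@values
    names(v) <- object@sampleIds
    v
})

#' @rdname accessors
#' @export
setMethod("responseOrientation", "DrugResponse",
          function(object) object@orientation)

#' @rdname accessors
#' @export
setMethod("classLabels", "SampleLabels", function(object) {
    l <- object@labels
    names(l) <- object@sampleIds
    l
})

#' @rdname accessors
#' @export
setMethod("zscores", "SampleLabels", function(object) {
    z <- object@zscores
    names(z) <- object@sampleIds
    z
})

#' @rdname accessors
#' @export
setMethod("rankedGenes", "FeatureRanking", function(object) object@geneIds)

#' @rdname accessors
#' @export
setMethod("rankingScores", "FeatureRanking", function(object) {
    s <- object@scores
    if (length(s)) names(s) <- object@geneIds
    s
})

#' @rdname accessors
#' @export
setMethod("rankingMethod", "FeatureRanking", function(object) object@method)

#' @rdname accessors
#' @export
setMethod("informativeGenes", "GroundTruth",
          function(object) object@informativeGenes)

#' @rdname accessors
#' @export
setMethod("geneWeights", "GroundTruth", function(object) object@geneWeights)

#' @rdname accessors
#' @export
setMethod("featureIds", "DrugResponseModel", function(object) object@featureIds)

#' @rdname accessors
#' @export
setMethod("gridTable", "CVResult", function(object) object@gridTable)

#' @rdname accessors
#' @export
setMethod("bestModelSpec", "CVResult", function(object) object@best)

#' @rdname accessors
#' @export
setMethod("bestAccuracy", "CVResult", function(object) object@bestAccuracy)

#' @rdname accessors
#' @export
setMethod("accuracyProfile", "CVResult", function(object) object@profile)

#' @rdname accessors
#' @export
setMethod("transferAccuracy", "TransferReport",
          function(object) object@accuracy)

#' @rdname accessors
#' @export
setMethod("transferAuc", "TransferReport", function(object) object@auc)

#' @rdname accessors
#' @export
setMethod("perSampleTable", "TransferReport", function(object) object@perSample)

#' @rdname accessors
#' @export
setMethod("overlapCounts", "OverlapTable", function(object) object@table)

setMethod("show", "DrugResponse", function(object) {
    cat("DrugResponse:", length(object@sampleIds), "samples,",
        "orientation =", object@orientation, "\n")
})

setMethod("show", "SampleLabels", function(object) {
    cat("SampleLabels (threshold", object@threshold, "SD):\n")
    print(table(object@labels))
})

setMethod("show", "FeatureRanking", function(object) {
    cat("FeatureRanking (", object@method, "): ",
        length(object@geneIds), " genes; top 5: ",
        paste(utils::head(object@geneIds, 5), collapse = ", "), "\n",
        sep = "")
})

setMethod("show", "DrugScreen", function(object) {
    callNextMethod()
    ori <- S4Vectors::metadata(object)$orientation
    if (!is.null(ori)) cat("response orientation:", ori, "\n")
    gt <- S4Vectors::metadata(object)$groundTruth
    if (!is.null(gt))
        cat("synthetic ground truth:", length(gt@informativeGenes),
            "informative genes\n")
})

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth:", length(object@informativeGenes),
        "informative genes")
    if (length(object@batchShift)) cat("; batch parameters recorded")
    cat("\n")
})

setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf(paste0("SyntheticSpec: %d samples x %d genes, ",
                       "%d informative (effect %.3g), noiseSd %.3g, ",
                       "batchShift %.3g, batchScale %.3g, seed %d\n"),
                object@nSamples, object@nGenes, object@nInformative,
                object@effectSize, object@noiseSd, object@batchShift,
                object@batchScale, object@seed))
})

setMethod("show", "DrugResponseModel", function(object) {
    cat(sprintf(paste0("DrugResponseModel: %s kernel, cost = %.4g, ",
                       "gamma = %.4g, %d features, ",
                       "training accuracy %.4f\n"),
                object@kernel, object@cost, object@gamma,
                length(object@featureIds), object@trainAccuracy))
})

setMethod("show", "CVResult", function(object) {
    b <- object@best
    cat(sprintf(paste0("CVResult: %d x %d-fold CV, %d grid cells; best ",
                       "accuracy %.4f at nFeatures = %d, cost = %.4g, ",
                       "gamma = %.4g\n"),
                object@repeats, object@folds, nrow(object@gridTable),
                object@bestAccuracy, b$nFeatures, b$cost, b$gamma))
})

setMethod("show", "TransferReport", function(object) {
    cat(sprintf(paste0("TransferReport: %d samples, accuracy %.4f, ",
                       "AUC %.4f, Welch t = %.4g (df %.3g), p = %.4g\n"),
                nrow(object@perSample), object@accuracy, object@auc,
                object@tStat, object@tDf, object@tPvalue))
})

setMethod("show", "OverlapTable", function(object) {
    cat(sprintf("OverlapTable: %d bins of %d over a universe of %d genes\n",
                object@nBins, object@binSize, object@universeSize))
    print(object@table, row.names = FALSE)
})
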