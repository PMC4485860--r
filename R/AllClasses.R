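#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata
NULL

.ORIENTATIONS <- c("higher_is_sensitive", "higher_is_resistant")
.RANK_METHODS <- c("f_score", "svm_rfe", "rf_importance")

#' Per-sample continuous drug response with orientation
#'
#' Holds one continuous response value per cell line together with the
#' semantics of the readout: activity-area-like summaries increase with
#' sensitivity (`higher_is_sensitive`), IC50-like summaries increase with
#' resistance (`higher_is_resistant`).
#'
#' @slot sampleIds character, unique sample identifiers.
#' @slot values numeric, one finite response value per sample.
#' @slot orientation one of `"higher_is_sensitive"`, `"higher_is_resistant"`.
#' @exportClass DrugResponse
setClass("DrugResponse",
    representation(sampleIds = "character", values = "numeric",
                   orientation = "character"))

setValidity("DrugResponse", function(object) {
    if (length(object@sampleIds) != length(object@values))
        return("sampleIds and values must have equal length")
    if (anyDuplicated(object@sampleIds))
        return("duplicate sample ids")
    if (!all(is.finite(object@values)))
        return("response values must all be finite")
    if (length(object@orientation) != 1L ||
        !object@orientation %in% .ORIENTATIONS)
        return(sprintf("orientation must be one of: %s",
                       paste(.ORIENTATIONS, collapse = ", ")))
    TRUE
})

#' Three-way sample classification from z-scored response
#'
#' @slot sampleIds character sample identifiers.
#' @slot zscores numeric, the normalized response each label derives from.
#' @slot labels factor with levels sensitive, intermediate, resistant.
#' @slot threshold numeric, the SD cut used.
#' @exportClass SampleLabels
setClass("SampleLabels",
    representation(sampleIds = "character", zscores = "numeric",
                   labels = "factor", threshold = "numeric"))

setValidity("SampleLabels", function(object) {
    n <- length(object@sampleIds)
    if (length(object@zscores) != n || length(object@labels) != n)
        return("sampleIds, zscores and labels must have equal length")
    if (!identical(levels(object@labels),
                   c("sensitive", "intermediate", "resistant")))
        return("labels must have levels sensitive, intermediate, resistant")
    if (anyNA(object@labels))
        return("labels must be complete (every sample gets a class)")
    TRUE
})

#' Total ordering of genes by discriminative importance
#'
#' Rank 1 is the most important gene. `scores` (optional) are aligned to the
#' ranking order; for score-based methods the order is descending score with
#' ties broken lexicographically by gene id.
#'
#' @slot geneIds character, a permutation of the input gene universe.
#' @slot scores numeric, empty or one score per ranked gene.
#' @slot method one of `"f_score"`, `"svm_rfe"`, `"rf_importance"`.
#' @exportClass FeatureRanking
setClass("FeatureRanking",
    representation(geneIds = "character", scores = "numeric",
                   method = "character"))

setValidity("FeatureRanking", function(object) {
    if (anyDuplicated(object@geneIds))
        return("ranking contains duplicate gene ids")
    if (length(object@scores) &&
        length(object@scores) != length(object@geneIds))
        return("scores must be empty or aligned to geneIds")
    if (length(object@method) != 1L || !object@method %in% .RANK_METHODS)
        return(sprintf("method must be one of: %s",
                       paste(.RANK_METHODS, collapse = ", ")))
    TRUE
})

#' Expression cohort container
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding a genes-by-samples
#' continuous expression matrix in assay `"exprs"`, the per-sample drug
#' response in `colData` (column `response`), the response orientation in
#' `metadata(x)$orientation`, and — for synthetic cohorts — the generative
#' ground truth in `metadata(x)$groundTruth`.
#'
#' @exportClass DrugScreen
setClass("DrugScreen", contains = "SummarizedExperiment")

setValidity("DrugScreen", function(object) {
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        return("assay 'exprs' is required")
    m <- SummarizedExperiment::assay(object, "exprs")
    if (is.null(rownames(m)) || is.null(colnames(m)))
        return("expression matrix must have gene and sample ids as dimnames")
    if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
        return("duplicate gene or sample ids")
    if (!all(is.finite(m)))
        return("expression values must all be finite")
    ori <- S4Vectors::metadata(object)$orientation
    if (!is.null(ori) && !ori %in% .ORIENTATIONS)
        return("metadata orientation must be a valid response orientation")
    TRUE
})

#' Generative ground truth of a synthetic cohort
#'
#' @slot informativeGenes character ids of the planted informative genes.
#' @slot geneWeights named numeric, linear coefficients of the latent
#'   response on the informative genes.
#' @slot batchShift named numeric, realized per-gene additive offsets applied
#'   to cohort B (empty for a single cohort).
#' @slot batchScale named numeric, realized per-gene multiplicative factors
#'   applied to cohort B (empty for a single cohort).
#' @exportClass GroundTruth
setClass("GroundTruth",
    representation(informativeGenes = "character", geneWeights = "numeric",
                   batchShift = "numeric", batchScale = "numeric"))

setValidity("GroundTruth", function(object) {
    if (length(object@geneWeights) != length(object@informativeGenes))
        return("one weight per informative gene required")
    TRUE
})

#' Parameters of the synthetic cohort generator
#'
#' Defaults describe the study conditions emulated throughout the package:
#' 150 cell lines, 1000 genes of standard-normal background expression, 10
#' informative genes of per-gene effect 1.5 background SDs, unit response
#' noise, and — for the second cohort of a pair — per-gene location shifts of
#' scale 3 and lognormal scale factors of spread 1.25.
#'
#' @slot nSamples,nGenes,nInformative integer counts.
#' @slot effectSize numeric, magnitude of each informative gene's coefficient.
#' @slot noiseSd numeric >= 0, SD of the response noise.
#' @slot batchShift numeric >= 0, SD of cohort-B additive per-gene offsets.
#' @slot batchScale numeric > 0, spread of cohort-B multiplicative factors
#'   (1 = no scale effect).
#' @slot seed integer master seed; expanded into independent substreams.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
    representation(nSamples = "integer", nGenes = "integer",
                   nInformative = "integer", effectSize = "numeric",
                   noiseSd = "numeric", batchShift = "numeric",
                   batchScale = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
    if (object@nSamples < 4L) return("nSamples: must be >= 4")
    if (object@nGenes < 1L) return("nGenes: must be >= 1")
    if (object@nInformative < 0L || object@nInformative > object@nGenes)
        return("nInformative: must satisfy 0 <= nInformative <= nGenes")
    if (object@noiseSd < 0) return("noiseSd: must be >= 0")
    if (object@batchShift < 0) return("batchShift: must be >= 0")
    if (object@batchScale <= 0) return("batchScale: must be > 0")
    TRUE
})

#' A trained drug-response SVM with its feature list and scaling
#'
#' @slot featureIds ordered selected gene ids.
#' @slot center,scale named per-feature training mean and SD.
#' @slot kernel `"radial"` or `"linear"`.
#' @slot cost,gamma SVM hyperparameters (gamma ignored for linear).
#' @slot fit the underlying [e1071::svm] fit.
#' @slot scoreSign +1/-1 so that positive decision score means sensitive.
#' @slot trainAccuracy training-set accuracy of the frozen fit.
#' @slot fullRanking the [FeatureRanking] the features were drawn from
#'   (kept for downstream ranked-list comparisons), or NULL.
#' @exportClass DrugResponseModel
setClass("DrugResponseModel",
    representation(featureIds = "character", center = "numeric",
                   scale = "numeric", kernel = "character", cost = "numeric",
                   gamma = "numeric", fit = "ANY", scoreSign = "numeric",
                   trainAccuracy = "numeric", fullRanking = "ANY"))

setValidity("DrugResponseModel", function(object) {
    if (length(object@center) != length(object@featureIds) ||
        length(object@scale) != length(object@featureIds))
        return("center/scale must be aligned to featureIds")
    if (!object@kernel %in% c("radial", "linear"))
        return("kernel must be 'radial' or 'linear'")
    if (object@cost <= 0) return("cost must be > 0")
    TRUE
})

#' Result of a repeated cross-validated grid search
#'
#' @slot gridTable data.frame with columns nFeatures, cost, gamma,
#'   meanAccuracy, sdAccuracy (mean/SD over repeats).
#' @slot best list(nFeatures, cost, gamma, kernel), the argmax cell
#'   (ties: fewest features, then smallest cost, then smallest gamma).
#' @slot bestAccuracy the maximal mean accuracy.
#' @slot profile data.frame (nFeatures, accuracy): per feature count, the best
#'   mean accuracy over the (cost, gamma) grid.
#' @slot folds,repeats,seed the CV layout actually used.
#' @exportClass CVResult
setClass("CVResult",
    representation(gridTable = "data.frame", best = "list",
                   bestAccuracy = "numeric", profile = "data.frame",
                   folds = "integer", repeats = "integer", seed = "integer"))

#' Cross-cohort transfer evaluation report
#'
#' @slot perSample data.frame (sampleId, trueLabel, predictedLabel,
#'   decisionScore, zscore) over the non-intermediate validation samples.
#' @slot accuracy fraction of correct hard predictions.
#' @slot auc Mann-Whitney AUC of decision scores vs true labels
#'   (positive class = sensitive).
#' @slot tStat,tDf,tPvalue Welch two-sample t-test comparing the normalized
#'   continuous responses of predicted-sensitive vs predicted-resistant
#'   samples (NA when a predicted class is empty).
#' @exportClass TransferReport
setClass("TransferReport",
    representation(perSample = "data.frame", accuracy = "numeric",
                   auc = "numeric", tStat = "numeric", tDf = "numeric",
                   tPvalue = "numeric"))

#' Binned overlap of two gene rankings with Fisher exact p-values
#'
#' @slot table data.frame (bin, from, to, overlap, pValue).
#' @slot universeSize number of genes in the common universe.
#' @slot binSize,nBins the tiling of the top of the rankings.
#' @exportClass OverlapTable
setClass("OverlapTable",
    representation(table = "data.frame", universeSize = "integer",
                   binSize = "integer", nBins = "integer"))
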