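#' Construct a DrugResponse
#'
#' @param sampleIds character sample identifiers.
#' @param values numeric response values (activity-area- or IC50-like).
#' @param orientation `"higher_is_sensitive"` for activity-area-like
#'   readouts, `"higher_is_resistant"` for IC50-like readouts.
#' @return a [DrugResponse-class] object.
#' @examples
#' DrugResponse(paste0("S", 1:4), c(2.1, 0.3, -1, 4),
#'              orientation = "higher_is_sensitive")
#' @export
DrugResponse <- function(sampleIds, values,
                         orientation = c("higher_is_sensitive",
                                         "higher_is_resistant")) {
    orientation <- match.arg(orientation)
    if (!is.null(names(values)) && missing(sampleIds))
        sampleIds <- names(values)
    new("DrugResponse", sampleIds = as.character(sampleIds),
        values = unname(as.numeric(values)), orientation = orientation)
}

#' Construct a DrugScreen cohort
#'
#' @param exprs numeric genes-by-samples matrix with gene ids as rownames and
#'   sample ids as colnames.
#' @param response optional [DrugResponse-class] (or named numeric, combined
#'   with `orientation`) over the same samples.
#' @param orientation response orientation, used when `response` is numeric.
#' @param groundTruth optional [GroundTruth-class] for synthetic cohorts.
#' @return a [DrugScreen-class] object.
#' @export
DrugScreen <- function(exprs, response = NULL,
                       orientation = c("higher_is_sensitive",
                                       "higher_is_resistant"),
                       groundTruth = NULL) {
    exprs <- as.matrix(exprs)
    md <- list()
    cd <- S4Vectors::DataFrame(row.names = colnames(exprs))
    if (!is.null(response)) {
        if (!is(response, "DrugResponse"))
            response <- DrugResponse(sampleIds = colnames(exprs),
                                     values = response,
                                     orientation = match.arg(orientation))
        if (!identical(response@sampleIds, colnames(exprs))) {
            if (!setequal(response@sampleIds, colnames(exprs)))
                stop("response samples do not match expression samples")
            response@values <-
                response@values[match(colnames(exprs), response@sampleIds)]
            response@sampleIds <- colnames(exprs)
        }
        cd$response <- response@values
        md$orientation <- response@orientation
    }
    if (!is.null(groundTruth)) {
        stopifnot(is(groundTruth, "GroundTruth"))
        md$groundTruth <- groundTruth
    }
    new("DrugScreen",
        SummarizedExperiment::SummarizedExperiment(
            assays = list(exprs = exprs), colData = cd, metadata = md))
}

#' Construct a SyntheticSpec
#'
#' See [SyntheticSpec-class] for the meaning of each field; the defaults are
#' the package's reference simulation conditions.
#'
#' @param nSamples,nGenes,nInformative counts.
#' @param effectSize per-informative-gene coefficient magnitude, in SD units
#'   of the background expression.
#' @param noiseSd SD of the Gaussian noise added to the latent response.
#' @param batchShift SD of cohort-B per-gene additive offsets.
#' @param batchScale spread of cohort-B per-gene lognormal scale factors
#'   (1 = none).
#' @param seed integer master seed.
#' @return a [SyntheticSpec-class] object.
#' @examples
#' syntheticSpec(nSamples = 120, nGenes = 300, seed = 7)
#' @export
syntheticSpec <- function(nSamples = 150L, nGenes = 1000L,
                          nInformative = 10L, effectSize = 1.5,
                          noiseSd = 1, batchShift = 3, batchScale = 1.25,
                          seed = 1L) {
    new("SyntheticSpec", nSamples = as.integer(nSamples),
        nGenes = as.integer(nGenes), nInformative = as.integer(nInformative),
        effectSize = as.numeric(effectSize), noiseSd = as.numeric(noiseSd),
        batchShift = as.numeric(batchShift),
        batchScale = as.numeric(batchScale), seed = as.integer(seed))
}

#' Construct a FeatureRanking
#'
#' @param geneIds character, ranked gene ids (rank 1 first).
#' @param scores optional numeric scores aligned to `geneIds`.
#' @param method the ranking method.
#' @return a [FeatureRanking-class] object.
#' @export
FeatureRanking <- function(geneIds, scores = numeric(0),
                           method = c("f_score", "svm_rfe",
                                      "rf_importance")) {
    new("FeatureRanking", geneIds = as.character(geneIds),
        scores = unname(as.numeric(scores)), method = match.arg(method))
}
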