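# Plain-text interchange: expression / response / label / ranking tables.

#' Read and write the package's tab-separated interchange formats
#'
#' Expression: first column `gene_id`, remaining columns one per sample.
#' Response: columns `sample_id`, `response`, `orientation`.
#' Labels: columns `sample_id`, `zscore`, `label`.
#' Ranking: columns `rank`, `gene_id`, `score`, `method`.
#'
#' @param path file path.
#' @param x,r,labels,ranking the object to write.
#' @name tsv-io
NULL

#' @rdname tsv-io
#' @export
readExpressionTsv <- function(path) {
    d <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[1]]
    storage.mode(m) <- "double"
    m
}

#' @rdname tsv-io
#' @export
writeExpressionTsv <- function(x, path) {
    x <- as.matrix(x)
    d <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname tsv-io
#' @export
readResponseTsv <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    ori <- unique(d$orientation)
    if (length(ori) != 1L)
        stop("response file must carry a single orientation")
    DrugResponse(d$sample_id, d$response, orientation = ori)
}

#' @rdname tsv-io
#' @export
writeResponseTsv <- function(r, path) {
    stopifnot(is(r, "DrugResponse"))
    utils::write.table(
        data.frame(sample_id = r@sampleIds, response = r@values,
                   orientation = r@orientation, stringsAsFactors = FALSE),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname tsv-io
#' @export
writeLabelsTsv <- function(labels, path) {
    stopifnot(is(labels, "SampleLabels"))
    utils::write.table(
        data.frame(sample_id = labels@sampleIds, zscore = labels@zscores,
                   label = as.character(labels@labels),
                   stringsAsFactors = FALSE),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname tsv-io
#' @export
readRankingTsv <- function(path) {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    d <- d[order(d$rank), , drop = FALSE]
    FeatureRanking(d$gene_id,
                   if ("score" %in% names(d)) d$score else numeric(0),
                   method = unique(d$method))
}

#' @rdname tsv-io
#' @export
writeRankingTsv <- function(ranking, path) {
    stopifnot(is(ranking, "FeatureRanking"))
    s <- ranking@scores
    utils::write.table(
        data.frame(rank = seq_along(ranking@geneIds),
                   gene_id = ranking@geneIds,
                   score = if (length(s)) s else NA_real_,
                   method = ranking@method, stringsAsFactors = FALSE),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Writes `expression.tsv`, `response.tsv` and (when the cohort carries one)
#' `ground_truth.json`.
#'
#' @param cohort a [DrugScreen-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    stopifnot(is(cohort, "DrugScreen"))
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeExpressionTsv(exprs(cohort), file.path(dir, "expression.tsv"))
    writeResponseTsv(drugResponse(cohort), file.path(dir, "response.tsv"))
    gt <- groundTruth(cohort)
    if (!is.null(gt)) {
        jsonlite::write_json(
            list(informative_genes = gt@informativeGenes,
                 gene_weights = as.list(gt@geneWeights),
                 batch_shift = as.list(gt@batchShift),
                 batch_scale = as.list(gt@batchScale)),
            file.path(dir, "ground_truth.json"),
            auto_unbox = TRUE, digits = NA)
    }
    invisible(dir)
}

#' Read a cohort written by [writeCohort()]
#'
#' @param dir directory containing `expression.tsv` and `response.tsv`.
#' @return a [DrugScreen-class] (without ground truth).
#' @export
readCohort <- function(dir) {
    DrugScreen(readExpressionTsv(file.path(dir, "expression.tsv")),
               response = readResponseTsv(file.path(dir, "response.tsv")))
}
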