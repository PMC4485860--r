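#' @rdname defaults
#' @export
defaultRunConfig <- function() {
    list(threshold = 0.8, minClassSize = 5L,
         folds = 10L, repeats = 10L,
         costGrid = defaultCostGrid(), gammaGrid = defaultGammaGrid(),
         featureGrid = NULL,  # NULL = defaultFeatureGrid(universe)
         kernel = "radial", rankMethod = "svm_rfe",
         rankPerFold = TRUE, rfeCost = 1, rfeSchedule = "chunked",
         rfTrees = 500L,
         tGrouping = "predicted", overlapAlternative = "two.sided",
         overlapBinSize = 500L, overlapNBins = 3L,
         harmonize = TRUE, seed = 1L)
}

#' Build, validate and (de)serialize a run configuration
#'
#' A run configuration is a flat named list; unspecified fields take the
#' package defaults (which are the tuned protocol's values: 0.8 SD
#' threshold, 10 repeats of 10-fold CV, the shipped cost/gamma grids).
#' Configurations round-trip losslessly through YAML.
#'
#' @param ... fields overriding [defaultRunConfig()].
#' @param path a YAML file to read/write.
#' @param config a configuration list.
#' @return `runConfig()` returns the validated list; `readRunConfig()` /
#'   `writeRunConfig()` read and write YAML.
#' @export
runConfig <- function(...) {
    args <- list(...)
    cfg <- defaultRunConfig()
    cfg[names(args)] <- args  # keeps explicit NULLs (= use default)
    unknown <- setdiff(names(cfg), names(defaultRunConfig()))
    if (length(unknown))
        stop("unknown config fields: ", paste(unknown, collapse = ", "))
    stopifnot(cfg$threshold > 0, cfg$minClassSize >= 2,
              cfg$folds >= 2, cfg$repeats >= 1,
              all(cfg$costGrid > 0), all(cfg$gammaGrid > 0),
              cfg$kernel %in% c("radial", "linear"),
              cfg$rankMethod %in% .RANK_METHODS,
              cfg$tGrouping %in% c("predicted", "true"),
              cfg$overlapAlternative %in% c("two.sided", "greater"))
    cfg
}

#' @rdname runConfig
#' @export
readRunConfig <- function(path) {
    do.call(runConfig, yaml::read_yaml(path))
}

#' @rdname runConfig
#' @export
writeRunConfig <- function(config, path) {
    yaml::write_yaml(config, path)
    invisible(path)
}

writeManifest <- function(outDir, config, stage, files) {
    files <- files[file.exists(file.path(outDir, files))]
    manifest <- list(
        package = "drugRFE",
        version = as.character(utils::packageVersion("drugRFE")),
        stage = stage,
        seed = config$seed,
        config = config,
        checksums = as.list(tools::md5sum(file.path(outDir, files))),
        timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}

#' Run the training half of the workflow on one cohort
#'
#' Labels the cohort from its drug response, applies drug-level QC (a
#' discarded drug is a clean reported outcome, not an error), ranks genes,
#' tunes feature count and SVM parameters by repeated stratified CV, fits
#' the final classifier on all retained samples, and writes the model
#' archive (`model.rds`), the CV grid (`cv_grid.tsv`), the accuracy profile
#' (`cv_profile.tsv`), the gene ranking (`ranking.tsv`), a training report
#' (`train_report.json`) and a manifest to `outDir`.
#'
#' @param cohort a [DrugScreen-class] with response.
#' @param config a [runConfig()] list.
#' @param outDir output directory (created if needed).
#' @return list with `status` (`"ok"` or `"discarded"`), and for `"ok"`:
#'   `model` ([DrugResponseModel-class]), `cv` ([CVResult-class]),
#'   `ranking`, `labels`, `manifest`.
#' @export
runTrainPipeline <- function(cohort, config = runConfig(), outDir) {
    stopifnot(is(cohort, "DrugScreen"))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    lab <- discretizeResponse(normalizeResponse(drugResponse(cohort)),
                              config$threshold)
    writeLabelsTsv(lab, file.path(outDir, "labels.tsv"))
    qc <- qcDrug(lab, config$minClassSize)
    if (qc$discarded) {
        jsonlite::write_json(
            list(status = "discarded", classCounts = qc$classCounts),
            file.path(outDir, "train_report.json"),
            auto_unbox = TRUE, digits = NA, pretty = TRUE)
        manifest <- writeManifest(outDir, config, "train",
                                  c("labels.tsv", "train_report.json"))
        message("drug discarded: too few valid samples (",
                paste(qc$classCounts, collapse = "/"), ")")
        return(list(status = "discarded", labels = lab,
                    manifest = manifest))
    }
    x <- exprs(cohort)[, qc$retained, drop = FALSE]
    y <- classLabels(lab)[qc$retained]
    featureGrid <- if (is.null(config$featureGrid))
        defaultFeatureGrid(nrow(x)) else config$featureGrid
    cv <- gridSearchCV(x, y, featureGrid = featureGrid,
                       costGrid = config$costGrid,
                       gammaGrid = config$gammaGrid,
                       folds = config$folds, repeats = config$repeats,
                       seed = config$seed, kernel = config$kernel,
                       rankMethod = config$rankMethod,
                       rankPerFold = config$rankPerFold,
                       rfeCost = config$rfeCost,
                       rfeSchedule = config$rfeSchedule,
                       rfTrees = config$rfTrees)
    ranking <- switch(config$rankMethod,
        svm_rfe = svmRfe(x, y, cost = config$rfeCost,
                         schedule = config$rfeSchedule),
        f_score = fScore(x, y),
        rf_importance = rfImportance(x, y, nTrees = config$rfTrees,
                                     seed = deriveSeed(config$seed, 99L)))
    best <- bestModelSpec(cv)
    model <- trainClassifier(x, y, ranking, nFeatures = best$nFeatures,
                             kernel = best$kernel, cost = best$cost,
                             gamma = best$gamma)
    saveRDS(model, file.path(outDir, "model.rds"))
    utils::write.table(gridTable(cv), file.path(outDir, "cv_grid.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(accuracyProfile(cv),
                       file.path(outDir, "cv_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeRankingTsv(ranking, file.path(outDir, "ranking.tsv"))
    jsonlite::write_json(
        list(status = "ok", best = best, bestAccuracy = bestAccuracy(cv),
             trainAccuracy = model@trainAccuracy,
             classCounts = qc$classCounts),
        file.path(outDir, "train_report.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest <- writeManifest(outDir, config, "train",
        c("labels.tsv", "model.rds", "cv_grid.tsv", "cv_profile.tsv",
          "ranking.tsv", "train_report.json"))
    list(status = "ok", model = model, cv = cv, ranking = ranking,
         labels = lab, manifest = manifest)
}

#' Run the transfer half of the workflow against a second cohort
#'
#' Intersects the gene universes, harmonizes the two cohorts by
#' empirical-Bayes batch adjustment (unless `config$harmonize` is FALSE),
#' evaluates the cohort-A model on the adjusted cohort B, and — when the
#' common universe is large enough — independently ranks cohort B and
#' scores the binned ranked-list overlap. Writes `transfer_report.json`,
#' `per_sample.tsv`, optionally `overlap.tsv`, and a manifest.
#'
#' @param model a [DrugResponseModel-class] (or path to a `model.rds`).
#' @param cohortA the training cohort (its expression anchors the joint
#'   harmonization), [DrugScreen-class] or matrix.
#' @param cohortB the validation [DrugScreen-class] (needs a response).
#' @param config a [runConfig()] list.
#' @param outDir output directory.
#' @return list with `report` ([TransferReport-class]), `overlap`
#'   ([OverlapTable-class] or NULL) and `manifest`.
#' @export
runTransferPipeline <- function(model, cohortA, cohortB,
                                config = runConfig(), outDir) {
    if (is.character(model)) model <- readRDS(model)
    stopifnot(is(model, "DrugResponseModel"), is(cohortB, "DrugScreen"))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    xA <- if (is(cohortA, "DrugScreen")) exprs(cohortA) else
        as.matrix(cohortA)
    xB <- exprs(cohortB)
    if (config$harmonize) {
        # anchor the adjustment to the training cohort: the frozen model's
        # feature scaling lives in cohort A's frame
        adj <- harmonizeCohorts(xA, xB, reference = "a")
        xB <- adj$b
    } else {
        xB <- intersectGenes(xA, xB)$b
    }
    missing <- setdiff(featureIds(model), rownames(xB))
    if (length(missing))
        stop("model features absent from the common gene universe: ",
             paste(utils::head(missing, 5), collapse = ", "))
    report <- evaluateTransfer(model, xB, drugResponse(cohortB),
                               threshold = config$threshold,
                               minClassSize = config$minClassSize,
                               tGrouping = config$tGrouping)
    utils::write.table(perSampleTable(report),
                       file.path(outDir, "per_sample.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    overlap <- NULL
    rkA <- model@fullRanking
    if (!is.null(rkA)) {
        universe <- intersect(rankedGenes(rkA), rownames(xB))
        if (length(universe) >=
            config$overlapBinSize * config$overlapNBins) {
            labB <- discretizeResponse(
                normalizeResponse(drugResponse(cohortB)),
                config$threshold)
            qcB <- qcDrug(labB, config$minClassSize)
            if (!qcB$discarded) {
                yB <- classLabels(labB)[qcB$retained]
                xBr <- xB[universe, qcB$retained, drop = FALSE]
                rkB <- switch(config$rankMethod,
                    svm_rfe = svmRfe(xBr, yB, cost = config$rfeCost,
                                     schedule = config$rfeSchedule),
                    f_score = fScore(xBr, yB),
                    rf_importance = rfImportance(
                        xBr, yB, nTrees = config$rfTrees,
                        seed = deriveSeed(config$seed, 199L)))
                rkAr <- FeatureRanking(
                    rankedGenes(rkA)[rankedGenes(rkA) %in% universe],
                    method = rankingMethod(rkA))
                overlap <- overlapSignificance(
                    rkAr, rkB, binSize = config$overlapBinSize,
                    nBins = config$overlapNBins,
                    alternative = config$overlapAlternative)
                utils::write.table(overlapCounts(overlap),
                                   file.path(outDir, "overlap.tsv"),
                                   sep = "\t", quote = FALSE,
                                   row.names = FALSE)
            }
        }
    }
    jsonlite::write_json(
        list(accuracy = transferAccuracy(report), auc = transferAuc(report),
             t = report@tStat, df = report@tDf, p = report@tPvalue,
             harmonized = config$harmonize,
             nSamples = nrow(perSampleTable(report))),
        file.path(outDir, "transfer_report.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest <- writeManifest(outDir, config, "transfer",
        c("per_sample.tsv", "overlap.tsv", "transfer_report.json"))
    list(report = report, overlap = overlap, manifest = manifest)
}
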