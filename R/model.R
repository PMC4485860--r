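#' Default hyperparameter grids and discretization defaults
#'
#' The cost and gamma grids searched during model tuning, the repeated-CV
#' layout, and the response-discretization defaults used throughout the
#' package.
#'
#' @return `defaultCostGrid()` and `defaultGammaGrid()` return numeric
#'   vectors; `defaultFeatureGrid(universeSize)` returns the candidate
#'   feature counts clipped to the universe size; `defaultRunConfig()`
#'   returns the full default configuration as a named list.
#' @name defaults
NULL

#' @rdname defaults
#' @export
defaultCostGrid <- function() c(0.1, 1, 10, 100, 200, 300, 500, 700, 800,
                                1000)

#' @rdname defaults
#' @export
defaultGammaGrid <- function() c(0.1, 0.5, 1, 2, 3, 4, 5, 6, 7, 8)

#' @rdname defaults
#' @param universeSize number of genes available.
#' @export
defaultFeatureGrid <- function(universeSize) {
    grid <- c(1:20, 25, 30, 40, 50, 75, 100, 150, 200, 300, 500)
    unique(pmin(grid, universeSize))
}

#' Train a kernel SVM on the top-ranked genes
#'
#' Selects the `nFeatures` top genes of `ranking`, standardizes them by
#' training mean/SD, and fits a soft-margin SVM. The classifier exposes hard
#' sensitive/resistant calls and a continuous decision score oriented so
#' that positive means sensitive.
#'
#' @param x genes-by-samples training matrix.
#' @param labels sensitive/resistant labels per training sample.
#' @param ranking a [FeatureRanking-class] over the genes of `x`; defaults
#'   to the row order of `x`.
#' @param nFeatures number of top-ranked genes to use.
#' @param kernel `"radial"` (default, the tuned model's kernel) or
#'   `"linear"`.
#' @param cost,gamma SVM hyperparameters; `gamma` is ignored for the linear
#'   kernel.
#' @return a [DrugResponseModel-class].
#' @export
trainClassifier <- function(x, labels, ranking = NULL,
                            nFeatures = nrow(x),
                            kernel = c("radial", "linear"),
                            cost = 1, gamma = 0.1) {
    x <- as.matrix(x)
    kernel <- match.arg(kernel)
    if (cost <= 0) stop("cost must be > 0")
    if (kernel == "radial" && gamma <= 0) stop("gamma must be > 0")
    y <- asBinaryLabels(labels, colnames(x))
    if (!is.null(names(y))) x <- x[, names(y), drop = FALSE]
    if (is.null(ranking))
        ranking <- FeatureRanking(rownames(x), method = "svm_rfe")
    feats <- utils::head(rankedGenes(ranking), nFeatures)
    if (nFeatures > length(rankedGenes(ranking)) ||
        !all(feats %in% rownames(x)))
        stop("nFeatures exceeds the available gene universe")
    st <- featureStats(x[feats, , drop = FALSE])
    xs <- applyFeatureStats(x[feats, , drop = FALSE], st)
    fit <- e1071::svm(x = t(xs), y = y, kernel = kernel, cost = cost,
                      gamma = gamma, scale = FALSE)
    pr <- stats::predict(fit, t(xs), decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # libsvm's decision value is positive for the class named first in the
    # "first/second" column label; orient scores so positive = sensitive
    positive <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
    scoreSign <- if (positive == "sensitive") 1 else -1
    new("DrugResponseModel", featureIds = feats, center = st$center,
        scale = st$scale, kernel = kernel, cost = cost, gamma = gamma,
        fit = fit, scoreSign = scoreSign,
        trainAccuracy = mean(pr == y), fullRanking = ranking)
}

#' Predict drug sensitivity for new samples
#'
#' Applies the stored training scaling and SVM to new expression profiles.
#'
#' @param model a [DrugResponseModel-class].
#' @param x genes-by-samples matrix containing all of the model's features.
#' @return list with `labels` (factor sensitive/resistant, named by sample)
#'   and `scores` (numeric decision values, positive = sensitive side).
#' @export
predictResponse <- function(model, x) {
    stopifnot(is(model, "DrugResponseModel"))
    x <- as.matrix(x)
    missing <- setdiff(model@featureIds, rownames(x))
    if (length(missing))
        stop("features absent from input: ",
             paste(missing, collapse = ", "))
    xs <- (x[model@featureIds, , drop = FALSE] - model@center) / model@scale
    pr <- stats::predict(model@fit, t(xs), decision.values = TRUE)
    scores <- model@scoreSign * drop(attr(pr, "decision.values"))
    labels <- factor(as.character(pr), levels = c("sensitive", "resistant"))
    names(labels) <- names(scores) <- colnames(x)
    list(labels = labels, scores = scores)
}

# Stratified fold assignment: per class, shuffled members are dealt
# round-robin, so each fold's class ratio is within one member of
# proportional and every sample is tested exactly once.
stratifiedFolds <- function(y, folds, seed) {
    withr::with_seed(seed, {
        id <- integer(length(y))
        for (cl in levels(y)) {
            idx <- sample(which(y == cl))
            id[idx] <- rep_len(sample(folds), length(idx))
        }
        id
    })
}

#' Joint selection of feature count and SVM parameters by repeated CV
#'
#' Runs repeated stratified k-fold cross-validation over the grid of
#' (number of top-ranked features) x cost x gamma, and returns the mean
#' accuracy per cell, the per-feature-count accuracy profile, and the argmax
#' cell (ties broken toward fewer features, then smaller cost, then smaller
#' gamma). Folds are reshuffled each repeat from the seed. Defaults follow
#' the tuned protocol: 10 repeats of 10-fold CV over the shipped cost and
#' gamma grids.
#'
#' By default the gene ranking is recomputed inside every training fold
#' (leakage-free). Passing a precomputed `ranking` with `rankPerFold =
#' FALSE` reproduces the cheaper rank-once-on-all-samples protocol.
#'
#' @param x genes-by-samples matrix.
#' @param labels sensitive/resistant labels per sample.
#' @param featureGrid candidate numbers of top genes.
#' @param costGrid,gammaGrid candidate SVM parameters (gamma collapses to a
#'   single placeholder for the linear kernel).
#' @param folds,repeats CV layout; folds are reduced (with a message) if a
#'   class is smaller than `folds`.
#' @param seed integer seed driving all reshuffles.
#' @param kernel SVM kernel for the tuned model.
#' @param rankMethod ranking method used per fold.
#' @param ranking optional precomputed [FeatureRanking-class].
#' @param rankPerFold recompute the ranking per training fold?
#' @param rfeCost,rfeSchedule,rfTrees options passed to the ranking method.
#' @return a [CVResult-class].
#' @export
gridSearchCV <- function(x, labels,
                         featureGrid = defaultFeatureGrid(nrow(x)),
                         costGrid = defaultCostGrid(),
                         gammaGrid = defaultGammaGrid(),
                         folds = 10L, repeats = 10L, seed = 1L,
                         kernel = c("radial", "linear"),
                         rankMethod = c("svm_rfe", "f_score",
                                        "rf_importance"),
                         ranking = NULL, rankPerFold = is.null(ranking),
                         rfeCost = 1, rfeSchedule = "chunked",
                         rfTrees = 500L) {
    x <- as.matrix(x)
    kernel <- match.arg(kernel)
    rankMethod <- match.arg(rankMethod)
    if (!length(featureGrid) || !length(costGrid) || !length(gammaGrid))
        stop("grids must be non-empty")
    y <- asBinaryLabels(labels, colnames(x))
    if (!is.null(names(y))) x <- x[, names(y), drop = FALSE]
    if (any(table(y) < 2L))
        stop("each class needs at least 2 samples")
    folds <- as.integer(folds)
    if (min(table(y)) < folds) {
        folds <- as.integer(min(table(y)))
        message("reducing folds to ", folds,
                " (smallest class has that many members)")
    }
    featureGrid <- sort(unique(pmin(as.integer(featureGrid), nrow(x))))
    if (kernel == "linear") gammaGrid <- gammaGrid[1]

    rankFun <- function(xt, yt, seed)
        switch(rankMethod,
               svm_rfe = svmRfe(xt, yt, cost = rfeCost,
                                schedule = rfeSchedule),
               f_score = fScore(xt, yt),
               rf_importance = rfImportance(xt, yt, nTrees = rfTrees,
                                            seed = seed))
    if (is.null(ranking) && !rankPerFold)
        ranking <- rankFun(x, y, deriveSeed(seed, 99L))

    cells <- expand.grid(nFeatures = featureGrid, cost = costGrid,
                         gamma = gammaGrid, KEEP.OUT.ATTRS = FALSE)
    accRep <- matrix(NA_real_, nrow(cells), repeats)
    for (r in seq_len(repeats)) {
        foldId <- stratifiedFolds(y, folds, deriveSeed(seed, 1000L + r))
        correct <- numeric(nrow(cells))
        tested <- 0L
        for (f in seq_len(folds)) {
            tr <- foldId != f
            te <- !tr
            tested <- tested + sum(te)
            rk <- if (rankPerFold)
                rankFun(x[, tr, drop = FALSE], y[tr],
                        deriveSeed(seed, 2000L + r * folds + f))
            else ranking
            for (i in seq_len(nrow(cells))) {
                m <- trainClassifier(x[, tr, drop = FALSE], y[tr], rk,
                                     nFeatures = cells$nFeatures[i],
                                     kernel = kernel, cost = cells$cost[i],
                                     gamma = cells$gamma[i])
                p <- predictResponse(m, x[, te, drop = FALSE])
                correct[i] <- correct[i] + sum(p$labels == y[te])
            }
        }
        accRep[, r] <- correct / tested
    }
    cells$meanAccuracy <- rowMeans(accRep)
    cells$sdAccuracy <- apply(accRep, 1L, stats::sd)
    ord <- order(-cells$meanAccuracy, cells$nFeatures, cells$cost,
                 cells$gamma)
    best <- cells[ord[1], ]
    profile <- do.call(rbind, lapply(split(cells, cells$nFeatures),
        function(d) data.frame(nFeatures = d$nFeatures[1],
                               accuracy = max(d$meanAccuracy))))
    profile <- profile[order(profile$nFeatures), , drop = FALSE]
    rownames(profile) <- NULL
    new("CVResult", gridTable = cells,
        best = list(nFeatures = best$nFeatures, cost = best$cost,
                    gamma = best$gamma, kernel = kernel),
        bestAccuracy = best$meanAccuracy, profile = profile,
        folds = folds, repeats = as.integer(repeats),
        seed = as.integer(seed))
}
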