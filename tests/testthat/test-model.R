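test_that("a separable toy is fit perfectly and predictions are coherent", {
    d <- makeSeparableToy()
    m <- trainClassifier(d$x, d$y, cost = 10, gamma = 0.5)
    expect_identical(m@trainAccuracy, 1)
    p <- predictResponse(m, d$x)
    expect_identical(p$labels, d$y)
    # decision scores thresholded at zero reproduce the hard labels
    expect_identical(p$scores > 0, stats::setNames(d$y == "sensitive",
                                                   names(d$y)))
})

test_that("using the full universe equals a fit with no selection step", {
    withr::with_seed(17, {
        x <- matrix(rnorm(20 * 50), 20,
                    dimnames = list(sprintf("G%02d", 1:20),
                                    sprintf("S%02d", 1:50)))
        y <- stats::setNames(rep(c("sensitive", "resistant"), each = 25),
                             colnames(x))
    })
    rk <- FeatureRanking(rev(rownames(x)), method = "svm_rfe")
    mSel <- trainClassifier(x, y, rk, nFeatures = 20, cost = 1,
                            gamma = 0.1)
    mAll <- trainClassifier(x, y, NULL, cost = 1, gamma = 0.1)
    pSel <- predictResponse(mSel, x)
    pAll <- predictResponse(mAll, x)
    expect_identical(pSel$labels, pAll$labels)
    expect_equal(pSel$scores, pAll$scores, tolerance = 1e-10)
})

test_that("training validates its inputs", {
    d <- makeSeparableToy()
    expect_error(trainClassifier(d$x, d$y, nFeatures = 5),
                 "exceeds the available gene universe")
    expect_error(trainClassifier(d$x, stats::setNames(
        rep("sensitive", ncol(d$x)), colnames(d$x))), "both classes")
    expect_error(trainClassifier(d$x, d$y, cost = -1), "cost")
    m <- trainClassifier(d$x, d$y)
    expect_error(predictResponse(m, d$x[1, , drop = FALSE]), "G2")
})

test_that("CV accuracy sits at chance when labels are independent", {
    withr::with_seed(23, {
        x <- matrix(rnorm(100 * 200), 100,
                    dimnames = list(sprintf("G%03d", 1:100),
                                    sprintf("S%03d", 1:200)))
        y <- stats::setNames(sample(rep(c("sensitive", "resistant"), 100)),
                             colnames(x))
    })
    cv <- gridSearchCV(x, y, featureGrid = 100, costGrid = 1,
                       gammaGrid = 0.1, folds = 10, repeats = 1, seed = 5,
                       ranking = FeatureRanking(rownames(x),
                                                method = "f_score"),
                       rankPerFold = FALSE)
    expect_gte(bestAccuracy(cv), 0.35)
    expect_lte(bestAccuracy(cv), 0.65)
})

test_that("grid search is deterministic and its argmax is consistent", {
    d <- makeLabelledCohort(syntheticSpec(nSamples = 80, nGenes = 60,
                                          nInformative = 5, seed = 51),
                            minClassSize = 3)
    run <- function() gridSearchCV(d$x, d$y, featureGrid = c(5, 20),
                                   costGrid = c(1, 10), gammaGrid = 0.1,
                                   folds = 5, repeats = 2, seed = 77,
                                   rankMethod = "f_score")
    cv1 <- run()
    cv2 <- run()
    expect_identical(gridTable(cv1), gridTable(cv2))
    expect_identical(bestModelSpec(cv1), bestModelSpec(cv2))
    g <- gridTable(cv1)
    expect_equal(bestAccuracy(cv1), max(g$meanAccuracy))
    b <- bestModelSpec(cv1)
    top <- g[g$meanAccuracy == bestAccuracy(cv1), ]
    expect_identical(b$nFeatures, min(top$nFeatures))
    # the per-feature-count profile is the max over (cost, gamma)
    prof <- accuracyProfile(cv1)
    for (i in seq_len(nrow(prof)))
        expect_equal(prof$accuracy[i],
                     max(g$meanAccuracy[g$nFeatures == prof$nFeatures[i]]))
})

test_that("fold assignment partitions samples and is stratified", {
    y <- factor(rep(c("sensitive", "resistant"), c(37, 23)),
                levels = c("sensitive", "resistant"))
    for (s in 1:5) {
        f <- drugRFE:::stratifiedFolds(y, 10L, s)
        expect_identical(length(f), 60L)
        expect_true(all(tabulate(f, 10L) >= 4))  # 60/10 +/- stratification
        for (cl in levels(y)) {
            perFold <- tabulate(f[y == cl], 10L)
            expect_lte(diff(range(perFold)), 1)
        }
    }
})

test_that("folds are reduced with a message when a class is small", {
    d <- makeSeparableToy(n = 12)
    expect_message(
        cv <- gridSearchCV(d$x, d$y, featureGrid = 2, costGrid = 1,
                           gammaGrid = 0.1, folds = 10, repeats = 1,
                           seed = 1,
                           ranking = FeatureRanking(rownames(d$x),
                                                    method = "f_score"),
                           rankPerFold = FALSE),
        "reducing folds")
    expect_identical(cv@folds, 6L)
})
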