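toyXY <- function() {
    x <- rbind(G1 = c(1, 2, 3, 4), G2 = c(1, -1, 2, -2))
    colnames(x) <- paste0("S", 1:4)
    y <- stats::setNames(c("sensitive", "sensitive", "resistant",
                           "resistant"), colnames(x))
    list(x = x, y = y)
}

test_that("F-score reproduces worked values and its symmetries", {
    d <- toyXY()
    f <- rankingScores(fScore(d$x, d$y))
    # {1,2} vs {3,4}: numerator 2, denominator 1
    expect_identical(unname(f["G1"]), 2)
    # both class means equal the overall mean
    expect_identical(unname(f["G2"]), 0)
    # label swap leaves the statistic unchanged
    swapped <- stats::setNames(rev(d$y), names(d$y))
    expect_equal(rankingScores(fScore(d$x, swapped))[names(f)], f)
})

test_that("F-score is invariant to per-gene affine rescaling", {
    withr::with_seed(5, {
        x <- matrix(rnorm(30 * 20), 30,
                    dimnames = list(sprintf("G%02d", 1:30),
                                    sprintf("S%02d", 1:20)))
        y <- stats::setNames(rep(c("sensitive", "resistant"), each = 10),
                             colnames(x))
        f0 <- rankingScores(fScore(x, y))
        x2 <- x * 3.7 - 11  # a != 0 affine map, applied per gene
        expect_equal(rankingScores(fScore(x2, y)), f0, tolerance = 1e-12)
    })
})

test_that("F-score matches the literal formula transcription", {
    withr::with_seed(8, {
        for (rep in 1:5) {
            x <- matrix(rnorm(50 * 20), 50,
                        dimnames = list(sprintf("G%02d", 1:50),
                                        sprintf("S%02d", 1:20)))
            y <- stats::setNames(sample(rep(c("sensitive", "resistant"),
                                            c(8, 12))), colnames(x))
            want <- fScoreLiteral(x, y[colnames(x)] == "sensitive")
            names(want) <- rownames(x)
            got <- rankingScores(fScore(x, y))
            expect_equal(got, want[names(got)], tolerance = 1e-10)
        }
    })
})

test_that("F-score requires two classes of at least 2 samples", {
    d <- toyXY()
    expect_error(fScore(d$x, c(S1 = "sensitive", S2 = "resistant",
                               S3 = "resistant", S4 = "resistant")),
                 "at least 2")
})

test_that("SVM-RFE handles the base case and finds a dominant feature", {
    one <- svmRfe(toyXY()$x[1, , drop = FALSE], toyXY()$y)
    expect_identical(rankedGenes(one), "G1")
    expect_identical(attr(one, "iterations"), 0L)

    withr::with_seed(12, {
        n <- 100
        cls <- rep(c(1, -1), each = n / 2)
        x <- rbind(G1 = 2 * cls + rnorm(n, 0, 0.1),
                   G2 = rnorm(n), G3 = rnorm(n))
        colnames(x) <- sprintf("S%03d", 1:n)
        y <- stats::setNames(ifelse(cls > 0, "sensitive", "resistant"),
                             colnames(x))
        rk <- svmRfe(x, y)
        expect_identical(rankedGenes(rk)[1], "G1")
        # |w1| dominates in a direct one-shot linear SVM fit
        st <- list(center = rowMeans(x), scale = apply(x, 1, sd))
        fit <- e1071::svm(x = t((x - st$center) / st$scale), y = factor(y),
                          kernel = "linear", cost = 1, scale = FALSE)
        w <- drop(crossprod(fit$coefs, fit$SV))
        expect_identical(names(which.max(w^2)), "G1")
    })
})

test_that("literal schedule eliminates one feature per step", {
    withr::with_seed(13, {
        x <- matrix(rnorm(12 * 30), 12,
                    dimnames = list(sprintf("G%02d", 1:12),
                                    sprintf("S%02d", 1:30)))
        y <- stats::setNames(rep(c("sensitive", "resistant"), 15),
                             colnames(x))
        rk <- svmRfe(x, y, schedule = "literal")
        expect_identical(attr(rk, "iterations"), 11L)
        expect_setequal(rankedGenes(rk), rownames(x))
        # below the chunking cutoff both schedules coincide
        expect_identical(rankedGenes(svmRfe(x, y, schedule = "chunked")),
                         rankedGenes(rk))
    })
})

test_that("rankings are permutations of the gene universe", {
    d <- makeLabelledCohort(syntheticSpec(nSamples = 60, nGenes = 40,
                                          nInformative = 3, seed = 31),
                            minClassSize = 2)
    for (rk in list(fScore(d$x, d$y), svmRfe(d$x, d$y),
                    rfImportance(d$x, d$y, nTrees = 50, seed = 1))) {
        expect_setequal(rankedGenes(rk), rownames(d$x))
        expect_identical(anyDuplicated(rankedGenes(rk)), 0L)
    }
})

test_that("RF importance is seeded and collapses under permuted labels", {
    d <- makeLabelledCohort(syntheticSpec(nSamples = 120, nGenes = 300,
                                          nInformative = 10, seed = 41))
    r1 <- rfImportance(d$x, d$y, nTrees = 100, seed = 9)
    r2 <- rfImportance(d$x, d$y, nTrees = 100, seed = 9)
    expect_identical(rankedGenes(r1), rankedGenes(r2))
    expect_gte(topKRecall(r1, d$truth), 0.4)
    yPerm <- withr::with_seed(2, stats::setNames(sample(as.character(d$y)),
                                                 names(d$y)))
    rNull <- rfImportance(d$x, yPerm, nTrees = 100, seed = 9)
    expect_lte(topKRecall(rNull, d$truth), 0.2)  # chance is 10/300
})

test_that("SVM-RFE recovers planted informative genes", {
    recalls <- vapply(1:3, function(s) {
        d <- makeLabelledCohort(syntheticSpec(nSamples = 120, nGenes = 300,
                                              nInformative = 10,
                                              effectSize = 1.5, seed = s))
        topKRecall(svmRfe(d$x, d$y), d$truth)
    }, numeric(1))
    expect_gte(mean(recalls), 0.5)
})
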