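test_that("generation is deterministic and validated", {
    spec <- syntheticSpec(nSamples = 30, nGenes = 50, seed = 7)
    a <- generateCohort(spec)
    b <- generateCohort(spec)
    expect_identical(exprs(a), exprs(b))
    expect_identical(responseValues(drugResponse(a)),
                     responseValues(drugResponse(b)))
    expect_error(syntheticSpec(nSamples = 2), "nSamples")
    expect_error(syntheticSpec(nInformative = 11, nGenes = 10),
                 "nInformative")
    expect_error(syntheticSpec(noiseSd = -1), "noiseSd")
    expect_error(syntheticSpec(batchScale = 0), "batchScale")
})

test_that("changing one spec field leaves unrelated substreams untouched", {
    a <- generateCohort(syntheticSpec(nSamples = 30, nGenes = 50,
                                      noiseSd = 1, seed = 7))
    b <- generateCohort(syntheticSpec(nSamples = 30, nGenes = 50,
                                      noiseSd = 2, seed = 7))
    expect_identical(exprs(a), exprs(b))
    expect_identical(informativeGenes(groundTruth(a)),
                     informativeGenes(groundTruth(b)))
})

test_that("with no informative genes the response is pure noise", {
    coh <- generateCohort(syntheticSpec(nSamples = 200, nGenes = 50,
                                        nInformative = 0, noiseSd = 1,
                                        seed = 11))
    r <- responseValues(drugResponse(coh))
    cors <- apply(exprs(coh), 1L, stats::cor, y = r)
    # null correlations at n = 200: centred on zero, essentially all
    # below |r| = 0.2 (2.8 SDs of the null)
    expect_lt(median(abs(cors)), 0.1)
    expect_gte(mean(abs(cors) < 0.2), 0.95)
    expect_length(informativeGenes(groundTruth(coh)), 0)
})

test_that("informative genes linearly drive the response (OLS oracle)", {
    coh <- generateCohort(syntheticSpec(nSamples = 200, nGenes = 100,
                                        nInformative = 5, effectSize = 2,
                                        noiseSd = 0.1, seed = 3))
    gt <- groundTruth(coh)
    d <- data.frame(y = responseValues(drugResponse(coh)),
                    t(exprs(coh)[informativeGenes(gt), ]))
    fit <- summary(lm(y ~ ., data = d))
    expect_gt(fit$r.squared, 0.9)
    # fitted coefficients recover the planted weights
    expect_equal(unname(coef(lm(y ~ ., data = d))[-1]),
                 unname(geneWeights(gt)), tolerance = 0.05)
})

test_that("paired cohorts share signal with opposite response signs", {
    sp <- syntheticSpec(nSamples = 150, nGenes = 200, nInformative = 5,
                        effectSize = 1.5, seed = 21)
    pair <- generatePairedCohorts(sp, syntheticSpec(nSamples = 150,
                                                    nGenes = 250,
                                                    seed = 22),
                                  sharedSeed = 9)
    gt <- pair$groundTruth
    coefFor <- function(coh) {
        d <- data.frame(y = responseValues(drugResponse(coh)),
                        t(exprs(coh)[informativeGenes(gt), ]))
        coef(lm(y ~ ., data = d))[-1]
    }
    cA <- coefFor(pair$cohortA)
    cB <- coefFor(pair$cohortB)
    expect_true(all(sign(cA) == -sign(cB)))
    expect_identical(responseOrientation(drugResponse(pair$cohortA)),
                     "higher_is_sensitive")
    expect_identical(responseOrientation(drugResponse(pair$cohortB)),
                     "higher_is_resistant")
})

test_that("per-gene batch location gap matches the half-normal mean", {
    sp <- function(seed) syntheticSpec(nSamples = 200, nGenes = 2000,
                                       nInformative = 0, batchShift = 5,
                                       batchScale = 1, seed = seed)
    pair <- generatePairedCohorts(sp(1), sp(2), sharedSeed = 4)
    gap <- abs(rowMeans(exprs(pair$cohortB)) -
               rowMeans(exprs(pair$cohortA)))
    expect_equal(mean(gap), 5 * sqrt(2 / pi), tolerance = 0.05)
    # realized batch parameters are recorded in the ground truth
    expect_equal(mean(abs(pair$groundTruth@batchShift)), 5 * sqrt(2 / pi),
                 tolerance = 0.05)
})

test_that("without batch effects the cohorts differ only by sampling noise", {
    sp <- function(seed) syntheticSpec(nSamples = 200, nGenes = 500,
                                       nInformative = 0, batchShift = 0,
                                       batchScale = 1, seed = seed)
    pair <- generatePairedCohorts(sp(5), sp(6), sharedSeed = 2)
    gap <- rowMeans(exprs(pair$cohortB)) - rowMeans(exprs(pair$cohortA))
    # per-gene mean difference ~ N(0, 2/200)
    expect_lt(abs(mean(gap)), 0.02)
    expect_equal(sd(gap), sqrt(2 / 200), tolerance = 0.15)
})
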