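mkRank <- function(ids) FeatureRanking(ids, method = "f_score")

test_that("bin overlap handles identity, reversal and validation", {
    ids <- sprintf("G%04d", 1:3000)
    expect_identical(binOverlap(mkRank(ids), mkRank(ids)),
                     rep(500L, 3))
    expect_identical(binOverlap(mkRank(ids), mkRank(rev(ids)))[1], 0L)
    expect_error(binOverlap(mkRank(ids), mkRank(ids[-1])),
                 "same gene universe")
    expect_error(binOverlap(mkRank(ids[1:1000]), mkRank(ids[1:1000])),
                 "exceeds the universe")
})

test_that("random rankings overlap at the hypergeometric expectation", {
    ids <- sprintf("G%05d", 1:10000)
    overlaps <- withr::with_seed(31, vapply(1:20, function(i)
        binOverlap(mkRank(sample(ids)), mkRank(sample(ids)))[1],
        integer(1)))
    expect_equal(mean(overlaps), 500^2 / 10000, tolerance = 0.1)
})

test_that("Fisher exact p reproduces worked values and symmetries", {
    expect_equal(fisherExact2x2(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
                 tolerance = 1e-12)
    # proportional rows: the independence table is the mode
    expect_equal(fisherExact2x2(matrix(c(2, 3, 4, 6), 2)), 1)
    m <- matrix(c(7, 2, 3, 9), 2)
    expect_equal(fisherExact2x2(t(m)), fisherExact2x2(m),
                 tolerance = 1e-12)
    expect_error(fisherExact2x2(matrix(c(-1, 0, 0, 5), 2)),
                 "non-negative")
})

test_that("Fisher exact p matches hypergeometric enumeration", {
    withr::with_seed(37, {
        for (rep in 1:50) {
            m <- matrix(rpois(4, 6), 2)
            expect_equal(fisherExact2x2(m), fisherByEnumeration(m),
                         tolerance = 1e-10)
        }
    })
})

test_that("overlap significance flags identical and enriched rankings", {
    ids <- sprintf("G%05d", 1:10000)
    ot <- overlapSignificance(mkRank(ids), mkRank(ids))
    expect_identical(overlapCounts(ot)$overlap, rep(500L, 3))
    expect_true(all(overlapCounts(ot)$pValue < 1e-300))

    # planted agreement: 100 specific genes forced into both top bins
    withr::with_seed(41, {
        ids3 <- sprintf("G%04d", 1:3000)
        shared <- sample(ids3, 100)
        mk <- function() {
            rest <- sample(setdiff(ids3, shared))
            top <- sample(c(shared, rest[1:400]))
            mkRank(c(top, rest[-(1:400)]))
        }
        ot2 <- overlapSignificance(mk(), mk())
        expect_gt(overlapCounts(ot2)$overlap[1], 500^2 / 3000)
        expect_lt(overlapCounts(ot2)$pValue[1], 0.01)
    })
})

test_that("under the null the Fisher p is calibrated or conservative", {
    ids <- sprintf("G%05d", 1:10000)
    ps <- withr::with_seed(43, vapply(1:60, function(i) {
        overlapCounts(overlapSignificance(mkRank(sample(ids)),
                                          mkRank(sample(ids)),
                                          binSize = 500L,
                                          nBins = 1L))$pValue
    }, numeric(1)))
    expect_lte(mean(ps < 0.05), 0.12)
})

test_that("shared planted signal in paired cohorts enriches the top bin", {
    # 50 genes sharing the response variance are individually weak
    # (per-gene correlation at most 1/sqrt(50)), so the detection study
    # uses the larger calibration cohort size
    sp <- function(seed) syntheticSpec(nSamples = 500, nGenes = 3000,
                                       nInformative = 50, effectSize = 2,
                                       seed = seed)
    pair <- generatePairedCohorts(sp(61), sp(62), sharedSeed = 6)
    rankOf <- function(coh) {
        lab <- discretizeResponse(normalizeResponse(drugResponse(coh)))
        qc <- qcDrug(lab)
        fScore(exprs(coh)[, qc$retained], classLabels(lab)[qc$retained])
    }
    rkA <- rankOf(pair$cohortA)
    rkB <- rankOf(pair$cohortB)
    # align cohort B's ranking to cohort A's universe
    common <- intersect(rankedGenes(rkA), rankedGenes(rkB))
    restrict <- function(rk) FeatureRanking(
        rankedGenes(rk)[rankedGenes(rk) %in% common], method = "f_score")
    ot <- overlapSignificance(restrict(rkA), restrict(rkB))
    expect_gt(overlapCounts(ot)$overlap[1], 500^2 / 3000)
    expect_lt(overlapCounts(ot)$pValue[1], 0.01)
})
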