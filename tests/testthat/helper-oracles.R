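# Independent oracles, kept deliberately naive and separate from the
# package implementations they check.

# Literal transcription of the F-score definition: per-feature loop,
# explicit sums, (n-1) within-class denominators, whole-data mean.
fScoreLiteral <- function(x, positive) {
    vapply(seq_len(nrow(x)), function(i) {
        xp <- x[i, positive]
        xn <- x[i, !positive]
        xbar <- mean(x[i, ])
        num <- (mean(xp) - xbar)^2 + (mean(xn) - xbar)^2
        den <- sum((xp - mean(xp))^2) / (length(xp) - 1) +
            sum((xn - mean(xn))^2) / (length(xn) - 1)
        num / den
    }, numeric(1))
}

# AUC by exhaustive enumeration of all positive-negative pairs, ties 1/2.
aucByEnumeration <- function(scores, positive) {
    sp <- scores[positive]
    sn <- scores[!positive]
    total <- 0
    for (a in sp) for (b in sn)
        total <- total + (a > b) + 0.5 * (a == b)
    total / (length(sp) * length(sn))
}

# Two-sided Fisher exact p by hypergeometric enumeration: sum the
# probabilities of all tables (margins fixed) no more probable than the
# observed one.
fisherByEnumeration <- function(m) {
    r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
    lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
    support <- lo:hi
    probs <- stats::dhyper(support, c1, n - c1, r1)
    pObs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# A linearly separable toy cohort: two clusters at +/-3 in two genes.
makeSeparableToy <- function(n = 40L, seed = 1L) {
    withr::with_seed(seed, {
        cls <- rep(c("sensitive", "resistant"), each = n / 2)
        mu <- ifelse(cls == "sensitive", 3, -3)
        x <- rbind(G1 = mu + rnorm(n, 0, 0.3),
                   G2 = mu + rnorm(n, 0, 0.3))
        colnames(x) <- sprintf("S%03d", seq_len(n))
        list(x = x, y = stats::setNames(factor(cls,
            levels = c("sensitive", "resistant")), colnames(x)))
    })
}

# Generate a cohort, label it, and return the retained training pieces.
makeLabelledCohort <- function(spec,
                               orientation = "higher_is_sensitive",
                               threshold = 0.8, minClassSize = 5L) {
    coh <- generateCohort(spec, orientation)
    lab <- discretizeResponse(normalizeResponse(drugResponse(coh)),
                              threshold)
    qc <- qcDrug(lab, minClassSize)
    list(cohort = coh, labels = lab, qc = qc,
         x = exprs(coh)[, qc$retained, drop = FALSE],
         y = classLabels(lab)[qc$retained],
         truth = groundTruth(coh))
}

topKRecall <- function(ranking, truth, k = 10L) {
    length(intersect(utils::head(rankedGenes(ranking), k),
                     informativeGenes(truth))) /
        length(informativeGenes(truth))
}
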