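# Internal helpers: seed substreams, label coercion, feature scaling.

# Expand one master seed into independent substreams so that changing one
# simulation ingredient never scrambles the draws of another. Kept inside
# 32-bit signed integer range.
deriveSeed <- function(seed, stream) {
    s <- (as.double(seed) %% 2147483647) * 69621 + stream * 10007
    as.integer(s %% 2147483647L)
}

# Coerce labels (factor/character/SampleLabels) to a sensitive/resistant
# factor, dropping any intermediates; errors unless both classes present.
asBinaryLabels <- function(labels, sampleIds = NULL) {
    if (is(labels, "SampleLabels")) {
        l <- classLabels(labels)
        l <- l[l != "intermediate"]
        labels <- l
    }
    lv <- as.character(labels)
    nm <- names(labels)
    if (is.null(nm) && !is.null(sampleIds)) nm <- sampleIds
    keep <- lv %in% c("sensitive", "resistant")
    if (!all(keep)) {
        lv <- lv[keep]
        nm <- nm[keep]
    }
    y <- factor(lv, levels = c("sensitive", "resistant"))
    names(y) <- nm
    if (any(table(y) == 0L))
        stop("both classes (sensitive, resistant) must be present")
    y
}

# Per-feature training statistics; zero-SD features get scale 1 so they
# contribute a constant (zero after centering) instead of NaN.
featureStats <- function(x) {
    ctr <- rowMeans(x)
    sdv <- apply(x, 1L, stats::sd)
    sdv[sdv == 0] <- 1
    list(center = ctr, scale = sdv)
}

applyFeatureStats <- function(x, stats) {
    (x - stats$center) / stats$scale
}

# Deterministic ordering by descending score, ties by lexicographic gene id.
orderByScore <- function(geneIds, scores) {
    order(-scores, geneIds, method = "radix")
}
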