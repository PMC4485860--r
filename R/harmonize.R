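#' Restrict two expression matrices to their common gene universe
#'
#' Both matrices are subset to the intersection of their gene ids, in
#' lexicographic order; samples are untouched.
#'
#' @param a,b genes-by-samples matrices (or [DrugScreen-class] cohorts).
#' @return list of the two restricted matrices (`a`, `b`).
#' @export
intersectGenes <- function(a, b) {
    if (is(a, "DrugScreen")) a <- exprs(a)
    if (is(b, "DrugScreen")) b <- exprs(b)
    common <- sort(intersect(rownames(a), rownames(b)), method = "radix")
    if (!length(common))
        stop("gene universes have an empty intersection")
    list(a = a[common, , drop = FALSE], b = b[common, , drop = FALSE])
}

#' Empirical-Bayes batch adjustment (parametric location/scale)
#'
#' Removes per-gene location and scale differences between batches by
#' parametric empirical-Bayes shrinkage of batch effects (ComBat, via the
#' sva package): genes are standardized, per-gene-per-batch location and
#' scale estimates are shrunk toward normal / inverse-gamma priors, and the
#' adjusted values are back-transformed to the pooled gene mean and
#' variance.
#'
#' Contract beyond the underlying routine: a design with a single batch is
#' returned unchanged (nothing to adjust); any batch with fewer than two
#' samples is an error; genes with zero pooled variance cannot be
#' standardized and pass through unadjusted with a warning.
#'
#' By default every batch is pulled toward the pooled per-gene
#' distribution. When a classifier frozen on one batch is to be applied to
#' the other, set `reference` to the training batch: the adjustment then
#' maps the other batch into the reference batch's frame and leaves the
#' reference (essentially) unchanged, so the frozen model's feature scaling
#' still applies.
#'
#' @param x numeric genes-by-samples matrix (both batches combined).
#' @param batch factor/character of batch labels, one per sample (column).
#' @param reference optional batch level to anchor the adjustment to.
#' @return adjusted matrix, same dimensions and dimnames as `x`.
#' @export
ebBatchAdjust <- function(x, batch, reference = NULL) {
    x <- as.matrix(x)
    if (length(batch) != ncol(x))
        stop("one batch label per sample is required")
    batch <- droplevels(as.factor(batch))
    if (nlevels(batch) < 2L) {
        message("single batch: returning input unadjusted")
        return(x)
    }
    if (any(table(batch) < 2L))
        stop("every batch must contain at least 2 samples")
    if (!is.null(reference) && !reference %in% levels(batch))
        stop("reference must be one of the batch levels")
    v <- apply(x, 1L, stats::var)
    fixed <- v <= .Machine$double.eps
    if (any(fixed))
        warning(sum(fixed), " zero-variance gene(s) passed through ",
                "unadjusted")
    out <- x
    if (any(!fixed)) {
        adj <- suppressMessages(
            sva::ComBat(dat = x[!fixed, , drop = FALSE], batch = batch,
                        mod = NULL, par.prior = TRUE, prior.plots = FALSE,
                        ref.batch = reference))
        out[!fixed, ] <- adj
    }
    out
}

#' Harmonize two cohorts jointly on their common genes
#'
#' Convenience wrapper: intersects the gene universes, concatenates the
#' samples, runs [ebBatchAdjust()] with one batch per cohort, and splits the
#' adjusted matrix back. `reference = "a"` anchors the adjustment to the
#' first cohort (use this when a model frozen on cohort a will be applied
#' to cohort b).
#'
#' @param a,b genes-by-samples matrices (or [DrugScreen-class] cohorts).
#' @param reference `NULL` (pooled), `"a"` or `"b"`.
#' @return list of adjusted matrices `a` and `b` over the common genes.
#' @export
harmonizeCohorts <- function(a, b, reference = NULL) {
    common <- intersectGenes(a, b)
    if (length(intersect(colnames(common$a), colnames(common$b))))
        stop("cohorts share sample ids; samples must be distinct")
    merged <- cbind(common$a, common$b)
    batch <- rep(c("a", "b"), c(ncol(common$a), ncol(common$b)))
    adj <- ebBatchAdjust(merged, batch, reference = reference)
    list(a = adj[, colnames(common$a), drop = FALSE],
         b = adj[, colnames(common$b), drop = FALSE])
}
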