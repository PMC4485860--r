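#' F-score feature ranking
#'
#' The F-score of gene *i* is the squared separation of the class means from
#' the whole-data mean over the summed within-class variances:
#' \deqn{F(i) = \frac{(\bar x_i^{(+)} - \bar x_i)^2 + (\bar x_i^{(-)} -
#'   \bar x_i)^2}{\frac{1}{n_+-1}\sum_k (x_{k,i}^{(+)} - \bar x_i^{(+)})^2 +
#'   \frac{1}{n_--1}\sum_k (x_{k,i}^{(-)} - \bar x_i^{(-)})^2}}
#' A larger F-score marks a more discriminative gene. Genes whose within- and
#' between-class variation are both zero get F = 0; a positive numerator over
#' a zero denominator gives F = Inf (ranked first).
#'
#' @param x genes-by-samples matrix.
#' @param labels sensitive/resistant labels per sample (factor, character or
#'   [SampleLabels-class]; intermediates are dropped).
#' @return a [FeatureRanking-class] (method `"f_score"`), ranked by
#'   descending score, ties broken by gene id.
#' @examples
#' x <- rbind(G1 = c(1, 2, 3, 4), G2 = c(1, 3, 2, 4))
#' colnames(x) <- paste0("S", 1:4)
#' fScore(x, c(S1 = "sensitive", S2 = "sensitive",
#'             S3 = "resistant", S4 = "resistant"))
#' @export
fScore <- function(x, labels) {
    x <- as.matrix(x)
    y <- asBinaryLabels(labels, colnames(x))
    if (!is.null(names(y))) x <- x[, names(y), drop = FALSE]
    if (any(table(y) < 2L))
        stop("each class needs at least 2 samples")
    pos <- y == "sensitive"
    xp <- x[, pos, drop = FALSE]
    xn <- x[, !pos, drop = FALSE]
    mAll <- rowMeans(x)
    mPos <- rowMeans(xp)
    mNeg <- rowMeans(xn)
    num <- (mPos - mAll)^2 + (mNeg - mAll)^2
    den <- apply(xp, 1L, stats::var) + apply(xn, 1L, stats::var)
    f <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
    ord <- orderByScore(rownames(x), f)
    FeatureRanking(rownames(x)[ord], f[ord], method = "f_score")
}

#' SVM-RFE: recursive feature elimination with a linear SVM
#'
#' Repeatedly (i) fits a linear soft-margin SVM on the surviving features,
#' (ii) scores each feature by its squared weight in the primal solution,
#' and (iii) eliminates the lowest-weight feature(s); eliminated features
#' fill the ranking from the bottom, so rank 1 is the last survivor.
#' Features are centred and scaled by training statistics before fitting so
#' weights are comparable across genes.
#'
#' The `"literal"` schedule removes exactly one feature per step (k-1 fits
#' for k features). Because that is quadratic in the number of genes, the
#' default `"chunked"` schedule removes 10% of the survivors per step while
#' more than 200 survive, then one per step.
#'
#' @param x genes-by-samples matrix.
#' @param labels sensitive/resistant labels per sample.
#' @param cost soft-margin cost of the internal linear SVM.
#' @param schedule `"chunked"` (default) or `"literal"`.
#' @return a [FeatureRanking-class] (method `"svm_rfe"`); scores are the
#'   reverse rank (larger = survived longer).
#' @export
svmRfe <- function(x, labels, cost = 1, schedule = c("chunked", "literal")) {
    x <- as.matrix(x)
    schedule <- match.arg(schedule)
    y <- asBinaryLabels(labels, colnames(x))
    if (!is.null(names(y))) x <- x[, names(y), drop = FALSE]
    if (any(table(y) < 2L))
        stop("each class needs at least 2 samples")
    if (nrow(x) < 1L)
        stop("at least one feature is required")
    xs <- applyFeatureStats(x, featureStats(x))
    remaining <- rownames(x)
    tailRanks <- character(0)
    iter <- 0L
    while (length(remaining) > 1L) {
        iter <- iter + 1L
        fit <- tryCatch(
            e1071::svm(x = t(xs[remaining, , drop = FALSE]), y = y,
                       kernel = "linear", cost = cost, scale = FALSE),
            error = function(e)
                stop("SVM fit failed at RFE iteration ", iter, ": ",
                     conditionMessage(e)))
        w <- drop(crossprod(fit$coefs, fit$SV))
        crit <- w^2
        nEl <- if (schedule == "chunked" && length(remaining) > 200L)
            min(ceiling(0.1 * length(remaining)), length(remaining) - 1L)
        else 1L
        ord <- orderByScore(remaining, crit)  # best first
        drop_ <- remaining[utils::tail(ord, nEl)]
        tailRanks <- c(drop_, tailRanks)
        remaining <- remaining[utils::head(ord, length(remaining) - nEl)]
    }
    ranking <- c(remaining, tailRanks)
    out <- FeatureRanking(ranking, rev(seq_along(ranking)),
                          method = "svm_rfe")
    attr(out, "iterations") <- iter
    out
}

#' Random-forest importance ranking
#'
#' Ranks genes by mean decrease in Gini impurity from a seeded random
#' forest of classification trees, each grown on a bootstrap sample with
#' random feature subsets at every split.
#'
#' @param x genes-by-samples matrix.
#' @param labels sensitive/resistant labels per sample.
#' @param nTrees number of trees, default 500.
#' @param seed integer seed; the ranking is deterministic given the seed.
#' @return a [FeatureRanking-class] (method `"rf_importance"`).
#' @export
rfImportance <- function(x, labels, nTrees = 500L, seed = 1L) {
    x <- as.matrix(x)
    y <- asBinaryLabels(labels, colnames(x))
    if (!is.null(names(y))) x <- x[, names(y), drop = FALSE]
    if (nTrees < 1L)
        stop("nTrees must be >= 1")
    fit <- withr::with_seed(as.integer(seed),
        randomForest::randomForest(x = t(x), y = y,
                                   ntree = as.integer(nTrees)))
    imp <- fit$importance[, "MeanDecreaseGini"]
    imp <- imp[rownames(x)]
    ord <- orderByScore(rownames(x), imp)
    FeatureRanking(rownames(x)[ord], unname(imp[ord]),
                   method = "rf_importance")
}
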