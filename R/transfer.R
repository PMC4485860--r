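#' Mann-Whitney ROC AUC of decision scores
#'
#' The probability that a uniformly chosen positive sample outranks a
#' uniformly chosen negative one, with ties counted one half (the
#' rank-statistic formulation of the area under the ROC curve).
#'
#' @param scores numeric decision scores, higher = more positive.
#' @param positive logical (TRUE = positive class) or a factor/character
#'   vector in which `"sensitive"` is the positive class.
#' @return the AUC in `[0, 1]`.
#' @examples
#' rocAuc(c(0.9, 0.4, 0.6, 0.2), c(TRUE, TRUE, FALSE, FALSE))  # 0.75
#' @export
rocAuc <- function(scores, positive) {
    if (!is.logical(positive))
        positive <- as.character(positive) == "sensitive"
    if (length(scores) != length(positive))
        stop("scores and labels must have equal length")
    n1 <- sum(positive)
    n0 <- sum(!positive)
    if (n1 == 0L || n0 == 0L)
        stop("both classes must be present to compute an AUC")
    r <- rank(scores)
    (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Satterthwaite degrees of freedom and a
#' two-sided p-value. When both groups are constant and equal, p = 1 is
#' returned with a warning instead of an error.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
welchTTest <- function(a, b) {
    if (length(a) < 2L || length(b) < 2L)
        stop("each group needs at least 2 values")
    if (stats::var(a) == 0 && stats::var(b) == 0) {
        if (mean(a) == mean(b)) {
            warning("both groups constant and equal; p = 1")
            return(list(t = 0, df = NA_real_, p = 1))
        }
        stop("both groups have zero variance")
    }
    ht <- stats::t.test(a, b, var.equal = FALSE)
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = ht$p.value)
}

#' Evaluate a trained classifier on an independent (harmonized) cohort
#'
#' The validation cohort is labelled by its own response (z-scored and
#' discretized with the orientation-appropriate mapping — for an IC50-like
#' readout high z means resistant), intermediates are dropped, the model
#' predicts the rest, and the transfer is scored by accuracy, the AUC of the
#' decision scores against the cohort's own labels, and a Welch t-test
#' comparing the normalized continuous responses of predicted-sensitive vs
#' predicted-resistant samples (`tGrouping = "predicted"`; the alternative
#' `"true"` groups decision scores by true label).
#'
#' @param model a [DrugResponseModel-class] trained on the first cohort.
#' @param x genes-by-samples matrix of the validation cohort (harmonized;
#'   must contain the model's features).
#' @param response [DrugResponse-class] of the validation cohort.
#' @param threshold discretization cut in SD units.
#' @param minClassSize drug-level QC limit; an error if the cohort fails it.
#' @param tGrouping see above.
#' @return a [TransferReport-class].
#' @export
evaluateTransfer <- function(model, x, response, threshold = 0.8,
                             minClassSize = 5L,
                             tGrouping = c("predicted", "true")) {
    stopifnot(is(model, "DrugResponseModel"), is(response, "DrugResponse"))
    tGrouping <- match.arg(tGrouping)
    x <- as.matrix(x)
    rN <- normalizeResponse(response)
    lab <- discretizeResponse(rN, threshold)
    qc <- qcDrug(lab, minClassSize)
    if (qc$discarded)
        stop("validation cohort fails drug-level QC (class counts: ",
             paste(qc$classCounts, collapse = "/"), ")")
    keep <- qc$retained
    missing <- setdiff(keep, colnames(x))
    if (length(missing))
        stop("expression missing for labelled samples: ",
             paste(utils::head(missing, 5), collapse = ", "))
    pred <- predictResponse(model, x[, keep, drop = FALSE])
    trueLab <- classLabels(lab)[keep]
    z <- zscores(lab)[keep]
    accuracy <- mean(as.character(pred$labels) == as.character(trueLab))
    auc <- rocAuc(pred$scores, as.character(trueLab) == "sensitive")
    grp <- if (tGrouping == "predicted") pred$labels else trueLab
    val <- if (tGrouping == "predicted") z else pred$scores
    tt <- list(t = NA_real_, df = NA_real_, p = NA_real_)
    if (all(table(grp)[c("sensitive", "resistant")] >= 2L)) {
        tt <- welchTTest(val[grp == "sensitive"], val[grp == "resistant"])
    } else {
        warning("a predicted class has fewer than 2 samples; ",
                "t-test not computed")
    }
    new("TransferReport",
        perSample = data.frame(sampleId = keep,
                               trueLabel = as.character(trueLab),
                               predictedLabel = as.character(pred$labels),
                               decisionScore = unname(pred$scores),
                               zscore = unname(z),
                               stringsAsFactors = FALSE),
        accuracy = accuracy, auc = auc, tStat = tt$t, tDf = tt$df,
        tPvalue = tt$p)
}
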