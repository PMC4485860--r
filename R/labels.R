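#' Normalize a drug response to zero mean and unit variance
#'
#' Responses are z-scored across all treated cell lines with the sample
#' standard deviation (n-1 denominator). The orientation flag is preserved.
#'
#' @param r a [DrugResponse-class].
#' @return a [DrugResponse-class] of z-scores.
#' @examples
#' r <- DrugResponse(paste0("S", 1:5), c(2, 1, 0, -1, -2))
#' responseValues(normalizeResponse(r))
#' @export
normalizeResponse <- function(r) {
    stopifnot(is(r, "DrugResponse"))
    if (length(r@values) < 2L)
        stop("at least 2 samples are required for normalization")
    s <- stats::sd(r@values)
    if (s == 0)
        stop("degenerate response: zero variance across samples")
    r@values <- (r@values - mean(r@values)) / s
    r
}

#' Discretize a normalized response into sensitive / intermediate / resistant
#'
#' For activity-area-like responses (`higher_is_sensitive`), z-scores at
#' least `threshold` SDs above the mean are sensitive and at least
#' `threshold` SDs below are resistant; for IC50-like responses
#' (`higher_is_resistant`) the mapping is mirrored. Boundaries are inclusive.
#' Everything in between is intermediate.
#'
#' @param r a normalized [DrugResponse-class] (see [normalizeResponse()]).
#' @param threshold the SD cut, default 0.8.
#' @return a [SampleLabels-class].
#' @examples
#' r <- normalizeResponse(DrugResponse(paste0("S", 1:5), c(2, 1, 0, -1, -2)))
#' classLabels(discretizeResponse(r))
#' @export
discretizeResponse <- function(r, threshold = 0.8) {
    stopifnot(is(r, "DrugResponse"))
    if (threshold <= 0)
        stop("threshold must be > 0")
    z <- r@values
    hi <- z >= threshold
    lo <- z <= -threshold
    lab <- rep("intermediate", length(z))
    if (r@orientation == "higher_is_sensitive") {
        lab[hi] <- "sensitive"
        lab[lo] <- "resistant"
    } else {
        lab[hi] <- "resistant"
        lab[lo] <- "sensitive"
    }
    new("SampleLabels", sampleIds = r@sampleIds, zscores = z,
        labels = factor(lab, levels = c("sensitive", "intermediate",
                                        "resistant")),
        threshold = threshold)
}

#' Drug-level QC: drop intermediates and flag drugs with too few samples
#'
#' Intermediate samples are removed; if either retained class holds fewer
#' than `minClassSize` samples the drug is flagged as discarded (a reported
#' outcome, not an error) — this is how drugs whose skewed response
#' distributions leave almost no valid samples are filtered out.
#'
#' @param labels a [SampleLabels-class].
#' @param minClassSize minimum per-class sample count, default 5.
#' @return list with `retained` (character sample ids, sensitive +
#'   resistant), `discarded` (logical), and `classCounts` (named integer).
#' @export
qcDrug <- function(labels, minClassSize = 5L) {
    stopifnot(is(labels, "SampleLabels"))
    if (minClassSize < 2L)
        stop("minClassSize must be >= 2")
    l <- classLabels(labels)
    counts <- table(l)[c("sensitive", "resistant")]
    counts[is.na(counts)] <- 0L
    discarded <- any(counts < minClassSize)
    retained <- if (discarded) character(0) else
        names(l)[l != "intermediate"]
    list(retained = retained, discarded = discarded,
         classCounts = c(sensitive = unname(counts["sensitive"]),
                         resistant = unname(counts["resistant"])))
}
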