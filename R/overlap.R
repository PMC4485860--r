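#' Same-tier overlap counts between two gene rankings
#'
#' Tiles the top of both rankings into `nBins` consecutive bins of
#' `binSize` ranks (bin b covers ranks (b-1)*binSize+1 .. b*binSize) and
#' counts, per bin, the genes the two rankings place in the same tier.
#'
#' @param rankA,rankB [FeatureRanking-class] objects over the same gene
#'   universe.
#' @param binSize genes per bin, default 500.
#' @param nBins number of bins, default 3 (i.e. the top 1500 genes).
#' @return integer vector of per-bin overlap counts.
#' @export
binOverlap <- function(rankA, rankB, binSize = 500L, nBins = 3L) {
    stopifnot(is(rankA, "FeatureRanking"), is(rankB, "FeatureRanking"))
    a <- rankedGenes(rankA)
    b <- rankedGenes(rankB)
    if (!setequal(a, b))
        stop("rankings must cover the same gene universe")
    if (binSize * nBins > length(a))
        stop("binSize * nBins exceeds the universe size")
    vapply(seq_len(nBins), function(k) {
        idx <- ((k - 1L) * binSize + 1L):(k * binSize)
        length(intersect(a[idx], b[idx]))
    }, integer(1))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact p-value with margins fixed: the sum of hypergeometric probabilities
#' of all tables as or less probable than the observed one.
#'
#' @param m 2x2 matrix of non-negative integer counts.
#' @param alternative `"two.sided"` (default) or `"greater"` (enrichment).
#' @return the p-value.
#' @examples
#' fisherExact2x2(matrix(c(5, 0, 0, 5), 2))  # 2/252
#' @export
fisherExact2x2 <- function(m, alternative = c("two.sided", "greater")) {
    alternative <- match.arg(alternative)
    m <- as.matrix(m)
    if (!all(dim(m) == 2L) || any(m < 0) || any(m != round(m)))
        stop("a 2x2 table of non-negative integer counts is required")
    stats::fisher.test(m, alternative = alternative)$p.value
}

#' Binned overlap significance of two gene rankings
#'
#' For each same-rank tier (by default three bins of 500, i.e. the top 1500
#' genes of each list), the overlap count k is tested against the common
#' universe of N genes with Fisher's exact test on the table
#' \preformatted{ [ k            binSize - k          ]
#'  [ binSize - k  N - 2*binSize + k    ]}
#' (membership of rankA's tier vs membership of rankB's tier).
#'
#' @inheritParams binOverlap
#' @param alternative sidedness of the Fisher test; `"two.sided"` default,
#'   `"greater"` tests enrichment only.
#' @return an [OverlapTable-class].
#' @export
overlapSignificance <- function(rankA, rankB, binSize = 500L, nBins = 3L,
                                alternative = c("two.sided", "greater")) {
    alternative <- match.arg(alternative)
    k <- binOverlap(rankA, rankB, binSize = binSize, nBins = nBins)
    N <- length(rankedGenes(rankA))
    p <- vapply(k, function(ki)
        fisherExact2x2(matrix(c(ki, binSize - ki, binSize - ki,
                                N - 2L * binSize + ki), 2L),
                       alternative = alternative),
        numeric(1))
    from <- (seq_len(nBins) - 1L) * binSize + 1L
    to <- seq_len(nBins) * binSize
    new("OverlapTable",
        table = data.frame(bin = sprintf("%d-%d", from, to),
                           from = from, to = to, overlap = k, pValue = p,
                           stringsAsFactors = FALSE),
        universeSize = as.integer(N), binSize = as.integer(binSize),
        nBins = as.integer(nBins))
}
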