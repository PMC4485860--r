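#' Generate a synthetic expression cohort with planted drug-response signal
#'
#' Background expression is i.i.d. standard normal per gene and sample. A
#' latent response is the linear combination of the planted informative
#' genes (coefficients of magnitude `effectSize`, random sign) plus Gaussian
#' noise of SD `noiseSd`. The returned response is the latent value for
#' activity-area-like readouts (`higher_is_sensitive`) and its negation for
#' IC50-like readouts (`higher_is_resistant`).
#'
#' The master seed is expanded into independent substreams for expression,
#' informative-gene choice/weights and response noise, so re-generation under
#' the same spec is bit-identical and changing one ingredient leaves the
#' others' draws untouched.
#'
#' @param spec a [syntheticSpec()].
#' @param orientation response readout orientation.
#' @return a [DrugScreen-class] with the ground truth in its metadata.
#' @examples
#' coh <- generateCohort(syntheticSpec(nSamples = 50, nGenes = 100, seed = 1))
#' informativeGenes(groundTruth(coh))
#' @export
generateCohort <- function(spec,
                           orientation = c("higher_is_sensitive",
                                           "higher_is_resistant")) {
    stopifnot(is(spec, "SyntheticSpec"))
    validObject(spec)
    orientation <- match.arg(orientation)
    geneIds <- sprintf("G%06d", seq_len(spec@nGenes))
    smpIds <- sprintf("S%04d", seq_len(spec@nSamples))

    x <- withr::with_seed(deriveSeed(spec@seed, 1L),
        matrix(stats::rnorm(spec@nGenes * spec@nSamples),
               nrow = spec@nGenes, dimnames = list(geneIds, smpIds)))
    gt <- drawGroundTruth(geneIds, spec@nInformative, spec@effectSize,
                          deriveSeed(spec@seed, 2L))
    latent <- latentResponse(x, gt, spec@noiseSd, deriveSeed(spec@seed, 4L))
    resp <- if (orientation == "higher_is_sensitive") latent else -latent
    DrugScreen(x, response = DrugResponse(smpIds, resp, orientation),
               groundTruth = gt)
}

#' Generate a pair of cohorts sharing planted signal but not platform
#'
#' Emulates a training resource and an independent validation resource
#' measured on different platforms: both cohorts share the informative genes
#' and their weights, cohort A reports an activity-area-like response
#' (higher = more sensitive), cohort B an IC50-like response (higher = more
#' resistant, i.e. the negated latent value), and cohort B's expression is
#' additionally distorted per gene as `a_g * x + b_g` with
#' `b_g ~ N(0, batchShift^2)` and `a_g` lognormal centred at 1 with spread
#' `log(batchScale)` (batch parameters taken from `specB`). Batch distortion
#' is applied after the latent response is computed, so the biology of B is
#' intact underneath the platform effect.
#'
#' The shared ingredients (informative set, weights, batch parameters) are
#' drawn from `sharedSeed` substreams; cohort-specific expression and noise
#' come from each spec's own seed. `specA`'s `nInformative`/`effectSize`
#' define the shared truth; informative genes are drawn from the common gene
#' universe (ids present in both cohorts).
#'
#' @param specA,specB [syntheticSpec()]s for the two cohorts (gene counts may
#'   differ; the universes overlap on the lower-numbered gene ids).
#' @param sharedSeed integer seed for the shared ground truth.
#' @return list with elements `cohortA`, `cohortB` ([DrugScreen-class]) and
#'   `groundTruth` ([GroundTruth-class], including realized batch
#'   parameters).
#' @export
generatePairedCohorts <- function(specA, specB = specA, sharedSeed = 1L) {
    stopifnot(is(specA, "SyntheticSpec"), is(specB, "SyntheticSpec"))
    validObject(specA); validObject(specB)
    genesA <- sprintf("G%06d", seq_len(specA@nGenes))
    genesB <- sprintf("G%06d", seq_len(specB@nGenes))
    common <- intersect(genesA, genesB)
    if (specA@nInformative > length(common))
        stop("shared informative genes must fit in the common gene universe")

    gt <- drawGroundTruth(common, specA@nInformative, specA@effectSize,
                          deriveSeed(sharedSeed, 2L))

    xA <- withr::with_seed(deriveSeed(specA@seed, 1L),
        matrix(stats::rnorm(specA@nGenes * specA@nSamples), nrow = specA@nGenes,
               dimnames = list(genesA, sprintf("A%04d",
                                               seq_len(specA@nSamples)))))
    latA <- latentResponse(xA, gt, specA@noiseSd, deriveSeed(specA@seed, 4L))
    cohA <- DrugScreen(xA,
        response = DrugResponse(colnames(xA), latA, "higher_is_sensitive"),
        groundTruth = gt)

    xB <- withr::with_seed(deriveSeed(specB@seed, 11L),
        matrix(stats::rnorm(specB@nGenes * specB@nSamples), nrow = specB@nGenes,
               dimnames = list(genesB, sprintf("B%04d",
                                               seq_len(specB@nSamples)))))
    latB <- latentResponse(xB, gt, specB@noiseSd, deriveSeed(specB@seed, 14L))
    bp <- withr::with_seed(deriveSeed(sharedSeed, 3L), {
        shift <- stats::rnorm(specB@nGenes, 0, specB@batchShift)
        scale <- exp(stats::rnorm(specB@nGenes, 0,
                                  abs(log(specB@batchScale))))
        list(shift = shift, scale = scale)
    })
    names(bp$shift) <- names(bp$scale) <- genesB
    xB <- xB * bp$scale + bp$shift

    gt@batchShift <- bp$shift
    gt@batchScale <- bp$scale
    cohB <- DrugScreen(xB,
        response = DrugResponse(colnames(xB), -latB, "higher_is_resistant"),
        groundTruth = gt)
    S4Vectors::metadata(cohA)$groundTruth <- gt
    list(cohortA = cohA, cohortB = cohB, groundTruth = gt)
}

drawGroundTruth <- function(universe, nInformative, effectSize, seed) {
    picks <- withr::with_seed(seed, {
        idx <- sort(sample(length(universe), nInformative))
        signs <- sample(c(-1, 1), nInformative, replace = TRUE)
        list(idx = idx, signs = signs)
    })
    ids <- universe[picks$idx]
    w <- effectSize * picks$signs
    names(w) <- ids
    new("GroundTruth", informativeGenes = ids, geneWeights = w,
        batchShift = numeric(0), batchScale = numeric(0))
}

latentResponse <- function(x, gt, noiseSd, noiseSeed) {
    n <- ncol(x)
    signal <- if (length(gt@informativeGenes))
        drop(gt@geneWeights %*% x[gt@informativeGenes, , drop = FALSE])
    else rep(0, n)
    noise <- withr::with_seed(noiseSeed, stats::rnorm(n, 0, noiseSd))
    unname(signal + noise)
}
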