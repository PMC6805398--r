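#' Build the reference signal profile
#'
#' Per-marker mean and standard deviation of total signal intensity over the
#' individuals of the designated reference breed. The mean is the denominator
#' of every log2 ratio downstream; the reference breed should therefore be a
#' large, low-variance, CNV-quiet population.
#'
#' @param cohort a [CnvCohort-class].
#' @param referenceBreed breed name present in `sampleInfo(cohort)$breed`.
#' @return a [ReferenceProfile-class].
#' @examples
#' sim <- simulateCohort(simConfig(seed = 3))
#' prof <- buildReferenceProfile(sim$cohort, "BelgianDraught")
#' prof
#' @export
buildReferenceProfile <- function(cohort, referenceBreed) {
    info <- sampleInfo(cohort)
    idx <- which(info$breed == referenceBreed)
    if (!length(idx))
        stop("reference breed ", sQuote(referenceBreed), " absent from labels")
    if (length(idx) < 2L)
        stop("need at least 2 reference individuals, found ", length(idx))
    x <- intensity(cohort)[, idx, drop = FALSE]
    mu <- rowMeans(x)
    if (any(mu <= 0))
        stop("reference mean is non-positive at marker ",
             names(markerMap(cohort))[which(mu <= 0)[1L]])
    sdv <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
    new("ReferenceProfile", markers = names(markerMap(cohort)),
        mean = unname(mu), sd = unname(sdv),
        nReference = length(idx), breed = referenceBreed)
}

#' Call per-marker SNP CNV gains and losses
#'
#' For every individual and marker, `log2Ratio = log2(intensity / reference
#' mean)`; markers with `log2Ratio >= gainThreshold` are called gains, those
#' with `log2Ratio <= -lossThreshold` losses (ties at the threshold are
#' calls), and everything else is left uncalled. Reference-breed individuals
#' are called against their own breed mean like everyone else, so the
#' reference breed can itself carry CNVs. Thresholding is strictly
#' per-marker; multi-marker evidence is enforced by [buildSegments()].
#'
#' The default +/-0.3 thresholds correspond to roughly 2.46 and 1.62 copies
#' and are standard array-CNV practice; the original study's commercial
#' caller does not document its internal settings, so these defaults make no
#' claim about them.
#'
#' @param cohort a [CnvCohort-class].
#' @param profile a [ReferenceProfile-class] covering the cohort's markers.
#' @param gainThreshold,lossThreshold positive log2-ratio thresholds.
#' @param exclude individual ids to skip (stands in for sample-level QC
#'   exclusions, e.g. call-rate failures, which are an input here).
#' @return `data.frame` with columns `individual`, `marker`, `chrom`, `pos`
#'   (1-based), `state` (`"gain"`/`"loss"`), `log2Ratio`; one row per call.
#' @examples
#' sim <- simulateCohort(simConfig(seed = 3))
#' prof <- buildReferenceProfile(sim$cohort, "BelgianDraught")
#' calls <- callSnpCnvs(sim$cohort, prof)
#' head(calls)
#' table(calls$state)
#' @export
callSnpCnvs <- function(cohort, profile, gainThreshold = 0.3,
                        lossThreshold = 0.3, exclude = character()) {
    stopifnot(is(profile, "ReferenceProfile"),
              gainThreshold > 0, lossThreshold > 0)
    map <- markerMap(cohort)
    if (!identical(profile@markers, names(map)))
        stop("reference profile does not match the cohort's marker map")
    x <- intensity(cohort)
    if (length(exclude)) x <- x[, !colnames(x) %in% exclude, drop = FALSE]
    if (any(x <= 0)) {
        bad <- which(x <= 0, arr.ind = TRUE)[1L, ]
        stop("non-positive intensity for individual ",
             colnames(x)[bad[2L]], " at marker ", rownames(x)[bad[1L]])
    }
    lr <- log2(x / profile@mean)
    hit <- which(lr >= gainThreshold | lr <= -lossThreshold, arr.ind = TRUE)
    if (!nrow(hit))
        return(data.frame(individual = character(), marker = character(),
                          chrom = character(), pos = integer(),
                          state = character(), log2Ratio = numeric()))
    v <- lr[hit]
    out <- data.frame(
        individual = colnames(x)[hit[, 2L]],
        marker = names(map)[hit[, 1L]],
        chrom = as.character(seqnames(map))[hit[, 1L]],
        pos = start(map)[hit[, 1L]],
        state = ifelse(v >= gainThreshold, "gain", "loss"),
        log2Ratio = v)
    out <- out[order(out$individual, out$chrom, out$pos), ]
    rownames(out) <- NULL
    out
}
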