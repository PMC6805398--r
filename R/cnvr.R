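#' Merge segment CNVs across the cohort into CNV regions
#'
#' CNVRs are the transitive closure of segments overlapping by at least 1 bp
#' across all individuals and states: each region spans from the leftmost
#' start to the rightmost end of its component segments. Bookended segments
#' (zero shared bases) are *not* merged. A region is `gain` when only gain
#' segments contribute, `loss` when only loss segments contribute, and
#' `both` otherwise (a mixed segment alone forces `both`).
#'
#' @param segments `GRanges` from [buildSegments()].
#' @param labels optional `data.frame(individual, breed, cluster)`; when
#'   given, per-breed carrier counts (individuals with >= 1 bp of overlapping
#'   segment) are attached as a matrix column `breedCarriers`.
#' @return `GRanges` of disjoint regions with metadata columns `state`,
#'   `nSegments`, `nCarriers` (and `breedCarriers` when labels are given).
#' @examples
#' sim <- simulateCohort(simConfig(seed = 3))
#' prof <- buildReferenceProfile(sim$cohort, "BelgianDraught")
#' segs <- buildSegments(callSnpCnvs(sim$cohort, prof), markerMap(sim$cohort))
#' cnvrs <- mergeToCnvrs(segs, sampleInfo(sim$cohort))
#' cnvrs
#' @export
mergeToCnvrs <- function(segments, labels = NULL) {
    if (!length(segments)) {
        out <- GRanges()
        mcols(out) <- DataFrame(state = character(), nSegments = integer(),
                                nCarriers = integer())
        return(out)
    }
    regions <- reduce(granges(segments), min.gapwidth = 0L,
                      ignore.strand = TRUE)
    ov <- findOverlaps(segments, regions, minoverlap = 1L)
    sIdx <- S4Vectors::queryHits(ov)
    rIdx <- S4Vectors::subjectHits(ov)
    states <- split(segments$state[sIdx], rIdx)
    regState <- vapply(states, function(s) {
        if (all(s == "gain")) "gain" else if (all(s == "loss")) "loss" else "both"
    }, character(1))
    nSeg <- vapply(states, length, integer(1))
    carriers <- split(segments$individual[sIdx], rIdx)
    ord <- as.character(seq_along(regions))
    mcols(regions)$state <- unname(regState[ord])
    mcols(regions)$nSegments <- unname(nSeg[ord])
    mcols(regions)$nCarriers <- unname(vapply(carriers[ord],
                                       function(x) length(unique(x)), integer(1)))
    if (!is.null(labels)) {
        breeds <- unique(labels$breed)
        bc <- t(vapply(carriers[ord], function(x) {
            b <- labels$breed[match(unique(x), labels$individual)]
            vapply(breeds, function(bb) sum(b == bb, na.rm = TRUE), integer(1))
        }, integer(length(breeds))))
        colnames(bc) <- breeds
        mcols(regions)$breedCarriers <- bc
    }
    regions
}

#' Average chromosome coverage by segment CNVs
#'
#' Per chromosome and state class, the mean over individuals of the
#' percentage of that chromosome covered by the union of the individual's
#' segments. Individuals without segments contribute zeros, so the
#' denominator is the full cohort, not just carriers. Mixed segments count
#' toward gain, loss and total alike.
#'
#' @param segments `GRanges` from [buildSegments()].
#' @param chromSizes named chromosome lengths (bp) covering every chromosome.
#' @param individuals character vector of all cohort individuals (defaults to
#'   the individuals present in `segments`, which omits zero-carriers — pass
#'   the full roster for cohort-level averages).
#' @return `data.frame` with columns `chrom`, `state`
#'   (`gain`/`loss`/`total`), `meanCoveragePct`.
#' @export
chromosomeCoverage <- function(segments, chromSizes,
                               individuals = unique(segments$individual)) {
    chr <- as.character(seqnames(segments))
    if (!all(chr %in% names(chromSizes)))
        stop("unknown chromosome: ",
             paste(setdiff(unique(chr), names(chromSizes)), collapse = ", "))
    states <- c("gain", "loss", "total")
    grid <- expand.grid(chrom = names(chromSizes), state = states,
                        stringsAsFactors = FALSE)
    grid$meanCoveragePct <- 0
    n <- length(individuals)
    if (!length(segments) || !n) return(grid)
    bys <- split(segments, segments$individual)
    for (id in names(bys)) {
        g <- bys[[id]]
        for (st in states) {
            keep <- switch(st, total = rep(TRUE, length(g)),
                           gain = g$state %in% c("gain", "mixed"),
                           loss = g$state %in% c("loss", "mixed"))
            u <- reduce(granges(g)[keep])
            if (!length(u)) next
            w <- tapply(width(u), as.character(seqnames(u)), sum)
            i <- match(paste(names(w), st), paste(grid$chrom, grid$state))
            grid$meanCoveragePct[i] <- grid$meanCoveragePct[i] +
                100 * as.numeric(w) / (chromSizes[names(w)] * n)
        }
    }
    grid
}

#' Chromosome share of segment CNV counts
#'
#' Percentage of segments of each state located on each chromosome,
#' regardless of chromosome size; shares sum to 100 within each state.
#'
#' @param segments non-empty `GRanges` from [buildSegments()].
#' @return `data.frame` with columns `chrom`, `state` (`gain`, `loss`,
#'   `mixed` and `all`), `sharePct`.
#' @export
chromosomeSegmentShare <- function(segments) {
    if (!length(segments)) stop("no segments: shares are undefined")
    chr <- as.character(seqnames(segments))
    out <- NULL
    for (st in c("gain", "loss", "mixed", "all")) {
        keep <- if (st == "all") rep(TRUE, length(segments))
                else segments$state == st
        if (!any(keep)) next
        tab <- table(chr[keep])
        out <- rbind(out, data.frame(chrom = names(tab), state = st,
                                     sharePct = 100 * as.numeric(tab) / sum(tab)))
    }
    rownames(out) <- NULL
    out
}
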