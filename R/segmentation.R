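#' @importFrom data.table data.table setkey rbindlist :=
NULL

#' Collapse SNP CNV calls into per-individual segment CNVs
#'
#' Per individual and chromosome, maximal runs of CNV-called markers that are
#' consecutive in marker-map order (allowing up to `maxGapMarkers` uncalled
#' markers inside a run) form one segment. Runs with fewer than `minMarkers`
#' called markers are discarded; this is where multi-marker evidence is
#' enforced, since calling itself is per-marker. A segment is a `gain` when
#' every contributing call is a gain, a `loss` when every call is a loss, and
#' `mixed` otherwise. Segment boundaries are the positions of the first and
#' last contributing marker.
#'
#' @param calls call table from [callSnpCnvs()].
#' @param map the cohort's marker map (`GRanges`, named by marker id).
#' @param minMarkers minimum called markers per segment (default 3, a common
#'   array-CNV floor).
#' @param maxGapMarkers maximum uncalled markers tolerated inside a run
#'   (default 0: strictly consecutive calls).
#' @return `GRanges` (1-based inclusive, first/last marker positions) with
#'   metadata columns `individual`, `state`, `nMarkers`, `meanLog2Ratio`;
#'   `metadata(x)$discardedCalls` counts calls lost to the `minMarkers` rule.
#' @examples
#' sim <- simulateCohort(simConfig(seed = 3))
#' prof <- buildReferenceProfile(sim$cohort, "BelgianDraught")
#' calls <- callSnpCnvs(sim$cohort, prof)
#' segs <- buildSegments(calls, markerMap(sim$cohort))
#' table(segs$state)
#' @export
buildSegments <- function(calls, map, minMarkers = 3L, maxGapMarkers = 0L) {
    stopifnot(minMarkers >= 1L, maxGapMarkers >= 0L)
    empty <- GRanges()
    mcols(empty) <- DataFrame(individual = character(), state = character(),
                              nMarkers = integer(), meanLog2Ratio = numeric())
    metadata(empty)$discardedCalls <- 0L
    if (!nrow(calls)) return(empty)
    gi <- match(calls$marker, names(map))
    if (anyNA(gi))
        stop("calls reference markers absent from the map: ",
             paste(utils::head(unique(calls$marker[is.na(gi)]), 3), collapse = ", "))
    dt <- data.table(individual = calls$individual, chrom = calls$chrom,
                     gi = gi, pos = calls$pos, state = calls$state,
                     lr = calls$log2Ratio)
    setkey(dt, individual, chrom, gi)
    gap <- maxGapMarkers + 1L
    dt[, run := cumsum(c(1L, as.integer(diff(gi) > gap))),
       by = c("individual", "chrom")]
    seg <- dt[, list(start = pos[1L], end = pos[.N], nMarkers = .N,
                     state = if (all(state == "gain")) "gain"
                             else if (all(state == "loss")) "loss"
                             else "mixed",
                     meanLog2Ratio = mean(lr)),
              by = c("individual", "chrom", "run")]
    discarded <- sum(seg$nMarkers[seg$nMarkers < minMarkers])
    seg <- seg[seg$nMarkers >= minMarkers, ]
    if (!nrow(seg)) { metadata(empty)$discardedCalls <- discarded; return(empty) }
    gr <- GRanges(seg$chrom, IRanges(seg$start, seg$end))
    mcols(gr) <- DataFrame(individual = seg$individual, state = seg$state,
                           nMarkers = as.integer(seg$nMarkers),
                           meanLog2Ratio = seg$meanLog2Ratio)
    sl <- seqlengths(map)
    if (!anyNA(sl) && length(sl))
        seqlengths(gr) <- sl[seqlevels(gr)]
    metadata(gr)$discardedCalls <- discarded
    gr
}

# union length of an individual's segments of the given state class;
# mixed segments carry both gain and loss evidence, so they count toward
# "total", "gain" and "loss" alike
.stateUnionWidth <- function(gr, stateClass) {
    keep <- switch(stateClass,
        total = rep(TRUE, length(gr)),
        gain = gr$state %in% c("gain", "mixed"),
        loss = gr$state %in% c("loss", "mixed"))
    sum(width(reduce(granges(gr)[keep])))
}

#' Per-breed summary of genome proportion affected by segment CNVs
#'
#' For each individual, the percentage of the autosomal genome covered by the
#' union of its segments — in total, by gains and by losses (mixed segments
#' count toward all three) — and per breed the mean and standard deviation of
#' those per-individual percentages. Individuals without any segment
#' contribute zeros.
#'
#' @param segments `GRanges` from [buildSegments()].
#' @param labels `data.frame(individual, breed, ...)` covering the cohort.
#' @param chromSizes named vector of autosome lengths (bp); must cover every
#'   chromosome carrying a segment. Sex chromosomes are not part of the
#'   genome size by construction.
#' @return `data.frame` with one row per breed: `breed`, `n`, and mean/sd of
#'   `totalPct`, `gainPct`, `lossPct`.
#' @export
segmentSummary <- function(segments, labels, chromSizes) {
    chr <- as.character(seqnames(segments))
    if (!all(chr %in% names(chromSizes)))
        stop("chromSizes is missing: ",
             paste(setdiff(unique(chr), names(chromSizes)), collapse = ", "))
    if (any(end(segments) > chromSizes[chr]))
        stop("segment extends beyond chromosome end")
    genome <- sum(chromSizes)
    per <- data.frame(individual = labels$individual, breed = labels$breed,
                      totalPct = 0, gainPct = 0, lossPct = 0)
    if (length(segments)) {
        bys <- split(segments, segments$individual)
        for (id in names(bys)) {
            i <- match(id, per$individual)
            if (is.na(i)) stop("segment individual ", id, " absent from labels")
            g <- bys[[id]]
            per$totalPct[i] <- 100 * .stateUnionWidth(g, "total") / genome
            per$gainPct[i] <- 100 * .stateUnionWidth(g, "gain") / genome
            per$lossPct[i] <- 100 * .stateUnionWidth(g, "loss") / genome
        }
    }
    agg <- lapply(split(per, per$breed), function(d) data.frame(
        breed = d$breed[1L], n = nrow(d),
        meanTotalPct = mean(d$totalPct), sdTotalPct = stats::sd(d$totalPct),
        meanGainPct = mean(d$gainPct), sdGainPct = stats::sd(d$gainPct),
        meanLossPct = mean(d$lossPct), sdLossPct = stats::sd(d$lossPct)))
    out <- do.call(rbind, agg)
    rownames(out) <- NULL
    attr(out, "perIndividual") <- per
    out
}
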