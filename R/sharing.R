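#' Within-group SNP CNV position frequencies
#'
#' Counts, for every (group, genome position, state), the individuals of the
#' group carrying that SNP CNV, and computes the within-group carrier
#' fraction. The group size is the number of labelled individuals, not the
#' number of carriers. Rows meeting `minFraction` (boundary inclusive) are
#' flagged `retained`; this is the "detected in at least 1% of the samples
#' within breed" filter that defines which positions a group reports.
#' Sub-threshold carrier rows are kept (flagged `FALSE`) because the
#' private/shared decision in [uniquePrivate()] is made on raw carrier
#' presence, not on the frequency filter.
#'
#' @param calls call table from [callSnpCnvs()].
#' @param labels `data.frame(individual, breed, cluster)`.
#' @param groupBy group positions by `"breed"` or `"cluster"`.
#' @param minFraction retention threshold on the carrier fraction
#'   (default 0.01).
#' @return `data.frame` with columns `group`, `chrom`, `pos`, `state`,
#'   `nCarriers`, `fraction`, `retained`; group sizes, the grouping level and
#'   `minFraction` are attached as attributes.
#' @examples
#' sim <- simulateCohort(simConfig(seed = 3))
#' prof <- buildReferenceProfile(sim$cohort, "BelgianDraught")
#' calls <- callSnpCnvs(sim$cohort, prof)
#' freq <- positionFrequency(calls, sampleInfo(sim$cohort), "breed")
#' head(freq[freq$retained, ])
#' @export
positionFrequency <- function(calls, labels, groupBy = c("breed", "cluster"),
                              minFraction = 0.01) {
    groupBy <- match.arg(groupBy)
    stopifnot(minFraction > 0, minFraction <= 1)
    grp <- labels[[groupBy]][match(calls$individual, labels$individual)]
    if (anyNA(grp))
        stop("unlabelled individuals in calls: ",
             paste(utils::head(unique(calls$individual[is.na(grp)]), 3),
                   collapse = ", "))
    sizes <- table(labels[[groupBy]])
    dt <- data.table(group = grp, chrom = calls$chrom, pos = calls$pos,
                     state = calls$state, individual = calls$individual)
    agg <- dt[, list(nCarriers = length(unique(individual))),
              by = c("group", "chrom", "pos", "state")]
    out <- as.data.frame(agg)
    out$fraction <- out$nCarriers / as.numeric(sizes[out$group])
    out$retained <- out$fraction >= minFraction
    out <- out[order(out$group, out$chrom, out$pos, out$state), ]
    rownames(out) <- NULL
    attr(out, "groupSizes") <- stats::setNames(as.integer(sizes), names(sizes))
    attr(out, "groupBy") <- groupBy
    attr(out, "minFraction") <- minFraction
    out
}

#' Identify unique private SNP CNVs
#'
#' A (position, state) retained in group *g* is unique private to *g* iff no
#' other group has a single carrier of that (position, state). Sharing is
#' thus decided on raw carrier presence (two or more individuals across
#' groups make a CNV shared), while the frequency filter only decides which
#' positions a group reports; gains and losses at the same position are
#' independent.
#'
#' @param freqTable the full table from [positionFrequency()] (all groups,
#'   one grouping level, one `minFraction`).
#' @param groupSizes named integer vector of group sizes; defaults to the
#'   attribute carried by `freqTable`.
#' @return a list:
#'   \describe{
#'     \item{positions}{retained rows of `freqTable` with a logical
#'       `private` column.}
#'     \item{report}{one row per group x state: `nPositions` (retained),
#'       `avgPerIndividual` (= nPositions / group size),
#'       `nUniquePrivate`, `pctUniquePrivate`.}
#'   }
#' @export
uniquePrivate <- function(freqTable, groupSizes = attr(freqTable, "groupSizes")) {
    if (is.null(groupSizes))
        stop("group sizes are required (build the table with positionFrequency)")
    key <- paste(freqTable$chrom, freqTable$pos, freqTable$state)
    groupsPerKey <- tapply(freqTable$group, key,
                           function(g) length(unique(g)))
    pos <- freqTable[freqTable$retained, , drop = FALSE]
    pos$private <- as.vector(groupsPerKey[paste(pos$chrom, pos$pos, pos$state)] == 1L)
    rownames(pos) <- NULL
    cells <- expand.grid(group = names(groupSizes), state = c("gain", "loss"),
                         stringsAsFactors = FALSE)
    report <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
        d <- pos[pos$group == cells$group[i] & pos$state == cells$state[i], ]
        n <- nrow(d); npriv <- sum(d$private)
        data.frame(group = cells$group[i], state = cells$state[i],
                   nPositions = n,
                   avgPerIndividual = n / as.numeric(groupSizes[cells$group[i]]),
                   nUniquePrivate = npriv,
                   pctUniquePrivate = if (n > 0) 100 * npriv / n else 0)
    }))
    rownames(report) <- NULL
    list(positions = pos, report = report)
}

#' Per-group totals and per-individual averages of retained SNP CNVs
#'
#' Reproduces the reporting arithmetic of the breed/cluster summary tables:
#' the bracketed per-individual average is the total number of retained
#' positions divided by the number of individuals in the group (an
#' alternative per-individual mean of raw call counts is available via
#' [averageCallsPerIndividual()]).
#'
#' @param freqTable table from [positionFrequency()] (or any `data.frame`
#'   with `group`, `state` and a logical `retained` column).
#' @param groupSizes named group sizes; defaults to the table's attribute.
#' @return `data.frame` with columns `group`, `state`, `nPositions`,
#'   `avgPerIndividual`.
#' @export
breedSummary <- function(freqTable, groupSizes = attr(freqTable, "groupSizes")) {
    if (is.null(groupSizes)) stop("group sizes are required")
    ret <- freqTable[freqTable$retained, , drop = FALSE]
    cells <- expand.grid(group = names(groupSizes), state = c("gain", "loss"),
                         stringsAsFactors = FALSE)
    out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
        n <- sum(ret$group == cells$group[i] & ret$state == cells$state[i])
        data.frame(group = cells$group[i], state = cells$state[i],
                   nPositions = n,
                   avgPerIndividual = n / as.numeric(groupSizes[cells$group[i]]))
    }))
    rownames(out) <- NULL
    out
}

#' Mean per-individual SNP CNV call counts (diagnostic)
#'
#' The alternative reading of the "average per individual": the mean over the
#' group's individuals of their raw per-individual call counts (zero for
#' individuals without calls).
#'
#' @inheritParams positionFrequency
#' @return `data.frame` with columns `group`, `state`, `meanCallsPerIndividual`.
#' @export
averageCallsPerIndividual <- function(calls, labels,
                                      groupBy = c("breed", "cluster")) {
    groupBy <- match.arg(groupBy)
    grp <- labels[[groupBy]]
    out <- NULL
    for (g in unique(grp)) for (st in c("gain", "loss")) {
        ids <- labels$individual[grp == g]
        cnt <- table(factor(calls$individual[calls$state == st &
                                             calls$individual %in% ids],
                            levels = ids))
        out <- rbind(out, data.frame(group = g, state = st,
                                     meanCallsPerIndividual = mean(cnt)))
    }
    rownames(out) <- NULL
    out
}

#' Chromosome profile of private SNP CNV carrier percentages
#'
#' For each unique private (position, state), the within-group carrier
#' percentage, plottable along chromosomes, plus a highlight list of
#' positions whose carrier percentage exceeds `highlightThreshold`
#' (strictly greater; default 20%, the level at which the emulated study
#' called out breed- and cluster-specific CNVs).
#'
#' @param privateResult result of [uniquePrivate()].
#' @param highlightThreshold carrier-percentage cutoff for the highlight list.
#' @return a list: `track` (`group`, `chrom`, `pos`, `state`, `carrierPct`)
#'   over all private positions, and `highlight` (the rows above threshold).
#' @export
privateChromosomeProfile <- function(privateResult, highlightThreshold = 20) {
    d <- privateResult$positions
    d <- d[d$private, , drop = FALSE]
    track <- data.frame(group = d$group, chrom = d$chrom, pos = d$pos,
                        state = d$state, carrierPct = 100 * d$fraction)
    rownames(track) <- NULL
    list(track = track,
         highlight = track[track$carrierPct > highlightThreshold, , drop = FALSE])
}
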