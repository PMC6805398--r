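#' Relative quantification by the 2^-ddCt method
#'
#' Per sample and target region, replicate Ct values are averaged, the
#' target is normalized against the reference gene
#' (`dCt = mean(Ct_target) - mean(Ct_reference)`), and the sample is
#' compared with the calibrator (`ddCt = dCt_sample - dCt_calibrator`);
#' the fold change is `2^-ddCt`. The calibrator must be a sample with
#' neither deletions nor duplications at any tested region, so its fold
#' change is exactly 1. Assay efficiency is assumed to be 100% (exact
#' doubling per cycle), as the method requires.
#'
#' @param ct `data.frame` with columns `sample`, `region`, `role`
#'   (`"target"` or `"reference"`), `ct` (cycles, positive finite); one row
#'   per replicate.
#' @param calibrator sample id of the calibrator individual.
#' @return `data.frame` with columns `sample`, `region`, `dCt`, `ddCt`,
#'   `foldChange`.
#' @examples
#' ct <- simulateCtTable(copyNumbers = cbind(s1 = c(r1 = 2), s2 = c(r1 = 1)),
#'                       calibrator = "s1", seed = 1, noiseSd = 0)
#' foldChange(ct, "s1")   # s2 fold change = 0.5
#' @export
foldChange <- function(ct, calibrator) {
    stopifnot(all(c("sample", "region", "role", "ct") %in% names(ct)),
              all(is.finite(ct$ct)), all(ct$ct > 0))
    if (!calibrator %in% ct$sample)
        stop("calibrator sample ", sQuote(calibrator), " absent from Ct table")
    mt <- function(s, r, role) {
        v <- ct$ct[ct$sample == s & ct$region == r & ct$role == role]
        if (!length(v)) return(NA_real_)
        mean(v)
    }
    combos <- unique(ct[ct$role == "target", c("sample", "region")])
    dct <- mapply(function(s, r) mt(s, r, "target") - mt(s, r, "reference"),
                  combos$sample, combos$region)
    combos$dCt <- unname(dct)
    if (anyNA(combos$dCt))
        stop("missing target or reference-gene Ct for some sample/region")
    cal <- combos[combos$sample == calibrator, ]
    calD <- stats::setNames(cal$dCt, cal$region)
    if (!all(combos$region %in% names(calD)))
        stop("calibrator has no measurement for region: ",
             paste(setdiff(combos$region, names(calD)), collapse = ", "))
    combos$ddCt <- combos$dCt - calD[combos$region]
    combos$foldChange <- 2^(-combos$ddCt)
    rownames(combos) <- NULL
    combos
}

#' Assign copy-number state from a qPCR fold change
#'
#' Diploid expectation is fold 1; a one-copy deletion halves it, a
#' duplication raises it to ~1.5. The default bins are centred on those
#' expectations: `< 0.25` homozygous deletion, `[0.25, 0.75)` one-copy
#' deletion, `[0.75, 1.25)` normal, `>= 1.25` duplication. Boundaries are
#' lower-inclusive so assignment is deterministic. The original assay's
#' fold-change thresholds were never printed; these cutpoints are
#' parameters, not a claim about them.
#'
#' @param fold numeric vector of positive fold changes.
#' @param cutpoints increasing cutpoints separating the four states.
#' @return character vector of states.
#' @export
copyState <- function(fold, cutpoints = c(0.25, 0.75, 1.25)) {
    stopifnot(length(cutpoints) == 3L, !is.unsorted(cutpoints, strictly = TRUE))
    if (any(!is.finite(fold) | fold <= 0))
        stop("fold changes must be positive and finite")
    states <- c("homozygous deletion", "one-copy deletion", "normal",
                "duplication")
    states[findInterval(fold, cutpoints) + 1L]
}

#' Array vs qPCR copy-state concordance
#'
#' Per region and overall, the fraction of matched (sample, region)
#' combinations where the array-derived and qPCR-derived states are
#' identical. The overall rate is the comparison-weighted mean (total
#' concordant over total compared), not the unweighted mean of per-region
#' rates.
#'
#' @param arrayStates,qpcrStates `data.frame(sample, region, state)` with
#'   identical (sample, region) key sets.
#' @return a list: `perRegion` (`region`, `nCompared`, `nConcordant`,
#'   `ratePct`) and `overall` (`nCompared`, `nConcordant`, `ratePct`).
#' @export
concordance <- function(arrayStates, qpcrStates) {
    ka <- paste(arrayStates$sample, arrayStates$region)
    kq <- paste(qpcrStates$sample, qpcrStates$region)
    unmatched <- c(setdiff(ka, kq), setdiff(kq, ka))
    if (length(unmatched))
        stop("unmatched sample/region combinations: ",
             paste(utils::head(unmatched, 5), collapse = ", "))
    m <- match(ka, kq)
    agree <- arrayStates$state == qpcrStates$state[m]
    per <- do.call(rbind, lapply(split(agree, arrayStates$region), function(a)
        data.frame(nCompared = length(a), nConcordant = sum(a),
                   ratePct = 100 * sum(a) / length(a))))
    per <- data.frame(region = rownames(per), per, row.names = NULL)
    list(perRegion = per,
         overall = data.frame(nCompared = length(agree),
                              nConcordant = sum(agree),
                              ratePct = 100 * sum(agree) / length(agree)))
}

#' Simulate a qPCR Ct table from known copy numbers
#'
#' Generates duplicate Ct measurements under the exact-doubling model
#' `Ct = base - log2(copy / 2) + noise` for the target assays and
#' `Ct = base + noise` for the reference gene, so that [foldChange()]
#' recovers `copy / 2` as noise goes to zero. Homozygous deletions are given
#' a residual-signal copy value of 0.05 to keep Ct finite.
#'
#' @param copyNumbers numeric matrix, regions x samples, of true copy
#'   numbers (calibrator column should be all 2).
#' @param calibrator calibrator sample id (a column of `copyNumbers`).
#' @param baseCt baseline cycle threshold (default 24).
#' @param noiseSd per-replicate Ct noise sd (default 0.05 cycles).
#' @param nReplicates replicates per assay (default 2, averaged downstream).
#' @param seed RNG seed.
#' @return Ct `data.frame` as accepted by [foldChange()].
#' @export
simulateCtTable <- function(copyNumbers, calibrator, baseCt = 24,
                            noiseSd = 0.05, nReplicates = 2L, seed = 1L) {
    stopifnot(calibrator %in% colnames(copyNumbers))
    set.seed(seed)
    out <- NULL
    for (s in colnames(copyNumbers)) for (r in rownames(copyNumbers)) {
        cp <- max(copyNumbers[r, s], 0.05)
        out <- rbind(out,
            data.frame(sample = s, region = r, role = "target",
                       replicate = seq_len(nReplicates),
                       ct = baseCt - log2(cp / 2) +
                           stats::rnorm(nReplicates, 0, noiseSd)),
            data.frame(sample = s, region = r, role = "reference",
                       replicate = seq_len(nReplicates),
                       ct = baseCt + stats::rnorm(nReplicates, 0, noiseSd)))
    }
    rownames(out) <- NULL
    out
}
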