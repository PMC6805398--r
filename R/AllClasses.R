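#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges granges reduce findOverlaps countOverlaps
#'   pintersect seqnames start end width strand
#' @importFrom GenomeInfoDb seqlevels seqlengths seqlengths<- seqnames
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges
#'   colData assayNames
NULL

#' Multi-breed SNP array cohort container
#'
#' `CnvCohort` extends [SummarizedExperiment::RangedSummarizedExperiment] with
#' two mandatory assays, `"intensity"` (total signal intensity per marker, in
#' arbitrary positive units) and `"baf"` (B-allele frequency in `[0, 1]`).
#' Rows are autosomal markers carried as a `GRanges` marker map, columns are
#' individuals with mandatory `breed` and `cluster` columns in `colData`.
#'
#' The marker map must be sorted with strictly increasing positions within
#' each chromosome; downstream segmentation relies on this ordering to define
#' "consecutive" markers.
#'
#' @slot ... see [SummarizedExperiment::RangedSummarizedExperiment].
#' @seealso [CnvCohort()] for construction, [simulateCohort()] for synthesis.
#' @export
setClass("CnvCohort", contains = "RangedSummarizedExperiment")

setValidity("CnvCohort", function(object) {
    msg <- character()
    an <- assayNames(object)
    if (!all(c("intensity", "baf") %in% an))
        msg <- c(msg, "assays must include 'intensity' and 'baf'")
    else {
        if (any(assay(object, "intensity") <= 0))
            msg <- c(msg, "all intensities must be > 0")
        b <- assay(object, "baf")
        if (any(b < 0 | b > 1))
            msg <- c(msg, "BAF values must lie in [0, 1]")
    }
    cd <- colData(object)
    if (!all(c("breed", "cluster") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'breed' and 'cluster'")
    rr <- rowRanges(object)
    if (length(rr)) {
        if (is.null(names(rr)))
            msg <- c(msg, "marker map must carry marker ids as names")
        bychr <- split(start(rr), as.character(seqnames(rr)))
        if (!all(vapply(bychr, function(p) all(diff(p) > 0), logical(1))))
            msg <- c(msg, "marker positions must be strictly increasing within chromosome")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a CnvCohort
#'
#' @param intensity numeric matrix, markers x individuals, all entries > 0.
#' @param baf numeric matrix of matching dimension with values in `[0, 1]`.
#' @param markerMap `GRanges` of width-1 marker positions (1-based), named by
#'   marker id, autosomes only, sorted by chromosome then position.
#' @param labels `data.frame` with columns `individual`, `breed`, `cluster`
#'   covering every column of `intensity`.
#' @param chromSizes optional named vector of chromosome lengths (bp) used to
#'   set `seqlengths` on the marker map.
#' @return A [CnvCohort-class] object.
#' @examples
#' sim <- simulateCohort(simConfig(seed = 1, breeds = data.frame(
#'     name = c("A", "B"), n = c(3, 3), cluster = c("c1", "c2")),
#'     referenceBreed = "A", nAutosomes = 1, nMarkersPerChrom = 50,
#'     plantedCnvrs = NULL))
#' sim$cohort
#' @export
CnvCohort <- function(intensity, baf, markerMap, labels, chromSizes = NULL) {
    stopifnot(is.matrix(intensity), is.matrix(baf),
              identical(dim(intensity), dim(baf)))
    if (nrow(intensity) != length(markerMap))
        stop("matrix rows must match the marker map")
    ids <- colnames(intensity)
    if (is.null(ids)) stop("intensity matrix must carry individual ids as colnames")
    m <- match(ids, labels$individual)
    if (anyNA(m))
        stop("unlabelled individuals: ", paste(ids[is.na(m)], collapse = ", "))
    cd <- DataFrame(breed = labels$breed[m], cluster = labels$cluster[m],
                    row.names = ids)
    if (!is.null(chromSizes)) {
        sl <- chromSizes[seqlevels(markerMap)]
        if (!anyNA(sl)) seqlengths(markerMap) <- sl
    }
    new("CnvCohort", SummarizedExperiment(
        assays = list(intensity = intensity, baf = baf),
        rowRanges = markerMap, colData = cd))
}

#' Per-marker reference signal profile
#'
#' Mean and standard deviation of total signal intensity across the reference
#' breed's individuals, one value per marker. The mean is the denominator of
#' every log2 ratio in [callSnpCnvs()].
#'
#' @slot markers character, marker ids (same order as the cohort map).
#' @slot mean numeric, per-marker mean intensity (> 0).
#' @slot sd numeric, per-marker standard deviation.
#' @slot nReference integer, number of reference individuals (>= 2).
#' @slot breed character, name of the reference breed.
#' @export
setClass("ReferenceProfile",
    representation(markers = "character", mean = "numeric", sd = "numeric",
                   nReference = "integer", breed = "character"))

setValidity("ReferenceProfile", function(object) {
    msg <- character()
    n <- length(object@markers)
    if (length(object@mean) != n || length(object@sd) != n)
        msg <- c(msg, "mean/sd must have one value per marker")
    if (any(object@mean <= 0))
        msg <- c(msg, "all reference means must be > 0")
    if (object@nReference < 2L)
        msg <- c(msg, "at least 2 reference individuals required")
    if (length(msg)) msg else TRUE
})

#' Principal component analysis result
#'
#' Deterministically signed PCA of an individuals x features matrix: the
#' largest-magnitude loading of each component is made positive so that
#' repeated runs and algebraically equivalent routes agree exactly.
#'
#' @slot scores numeric matrix, individuals x components.
#' @slot loadings numeric matrix, features x components.
#' @slot varianceExplained numeric, fraction of total variance per component
#'   over *all* components (sums to 1), of which the first `ncol(scores)` are
#'   retained in `scores`/`loadings`.
#' @seealso [runPca()]
#' @export
setClass("PcaResult",
    representation(scores = "matrix", loadings = "matrix",
                   varianceExplained = "numeric"))

setValidity("PcaResult", function(object) {
    msg <- character()
    if (abs(sum(object@varianceExplained) - 1) > 1e-8)
        msg <- c(msg, "varianceExplained must sum to 1")
    if (is.unsorted(-object@varianceExplained))
        msg <- c(msg, "components must be ordered by decreasing variance")
    if (ncol(object@scores) != ncol(object@loadings))
        msg <- c(msg, "scores and loadings must agree on component count")
    if (length(msg)) msg else TRUE
})
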