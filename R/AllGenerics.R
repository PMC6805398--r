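#' Accessors for cohort and result objects
#'
#' `intensity()` and `baf()` return the marker x individual assay matrices;
#' `markerMap()` the `GRanges` marker map; `sampleInfo()` the individual
#' labels as a `data.frame` with columns `individual`, `breed`, `cluster`.
#' `pcaScores()`, `pcaLoadings()` and `varianceExplained()` access
#' [PcaResult-class] slots.
#'
#' @param object a [CnvCohort-class] or [PcaResult-class] object.
#' @return the matrix, `GRanges` or `data.frame` named above.
#' @name accessors
#' @examples
#' sim <- simulateCohort(simConfig(seed = 1, breeds = data.frame(
#'     name = c("A", "B"), n = c(3, 3), cluster = c("c1", "c2")),
#'     referenceBreed = "A", nAutosomes = 1, nMarkersPerChrom = 20,
#'     plantedCnvrs = NULL))
#' dim(intensity(sim$cohort))
#' head(sampleInfo(sim$cohort))
NULL

#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' @rdname accessors
#' @export
setGeneric("baf", function(object) standardGeneric("baf"))

#' @rdname accessors
#' @export
setGeneric("markerMap", function(object) standardGeneric("markerMap"))

#' @rdname accessors
#' @export
setGeneric("sampleInfo", function(object) standardGeneric("sampleInfo"))

#' @rdname accessors
#' @export
setGeneric("pcaScores", function(object) standardGeneric("pcaScores"))

#' @rdname accessors
#' @export
setGeneric("pcaLoadings", function(object) standardGeneric("pcaLoadings"))

#' @rdname accessors
#' @export
setGeneric("varianceExplained", function(object) standardGeneric("varianceExplained"))

#' @rdname accessors
#' @export
setMethod("intensity", "CnvCohort", function(object) assay(object, "intensity"))

#' @rdname accessors
#' @export
setMethod("baf", "CnvCohort", function(object) assay(object, "baf"))

#' @rdname accessors
#' @export
setMethod("markerMap", "CnvCohort", function(object) rowRanges(object))

#' @rdname accessors
#' @export
setMethod("sampleInfo", "CnvCohort", function(object) {
    cd <- colData(object)
    data.frame(individual = rownames(cd), breed = cd$breed,
               cluster = cd$cluster, row.names = NULL)
})

#' @rdname accessors
#' @export
setMethod("pcaScores", "PcaResult", function(object) object@scores)

#' @rdname accessors
#' @export
setMethod("pcaLoadings", "PcaResult", function(object) object@loadings)

#' @rdname accessors
#' @export
setMethod("varianceExplained", "PcaResult", function(object) object@varianceExplained)

setMethod("show", "CnvCohort", function(object) {
    cat("CnvCohort:", nrow(object), "markers x", ncol(object), "individuals\n")
    cat("  chromosomes:", paste(seqlevels(rowRanges(object)), collapse = ", "), "\n")
    br <- table(colData(object)$breed)
    cat("  breeds:", paste(sprintf("%s (%d)", names(br), br), collapse = ", "), "\n")
    cl <- unique(colData(object)$cluster)
    cat("  clusters:", paste(cl, collapse = ", "), "\n")
})

setMethod("show", "ReferenceProfile", function(object) {
    cat("ReferenceProfile:", length(object@markers), "markers, breed",
        sQuote(object@breed), "(n =", paste0(object@nReference, ")\n"))
    cat("  mean intensity range:",
        sprintf("%.3f-%.3f", min(object@mean), max(object@mean)), "\n")
})

setMethod("show", "PcaResult", function(object) {
    k <- min(5L, length(object@varianceExplained))
    cat("PcaResult:", nrow(object@scores), "individuals,",
        ncol(object@scores), "components retained\n")
    cat("  variance explained:",
        paste(sprintf("PC%d %.1f%%", seq_len(k),
                      100 * object@varianceExplained[seq_len(k)]),
              collapse = ", "), "\n")
})
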