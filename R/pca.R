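#' Principal component analysis with deterministic sign convention
#'
#' Eigendecomposition of the (centered, optionally scaled) covariance of an
#' individuals x features matrix, computed via [stats::prcomp]. The sign of
#' each component is fixed by making its largest-magnitude loading positive,
#' so results are fully deterministic and comparable across runs and
#' implementations. Variance fractions are reported over *all* components
#' (they sum to 1) even when only `nComponents` are retained.
#'
#' @param x numeric matrix, individuals in rows (>= 2 rows and columns, no
#'   missing values).
#' @param center,scale passed to [stats::prcomp]; scaling a zero-variance
#'   column is an error naming the column.
#' @param nComponents number of components to retain (default: all).
#' @return a [PcaResult-class].
#' @examples
#' x <- matrix(rnorm(200), 20, 10)
#' res <- runPca(x, nComponents = 3)
#' res
#' sum(varianceExplained(res))
#' @export
runPca <- function(x, center = TRUE, scale = FALSE, nComponents = NULL) {
    x <- as.matrix(x)
    if (nrow(x) < 2L || ncol(x) < 2L)
        stop("PCA needs at least 2 rows and 2 columns")
    if (anyNA(x)) stop("matrix contains missing values; impute before PCA")
    if (scale) {
        v <- apply(x, 2L, stats::var)
        if (any(v == 0)) {
            nm <- colnames(x)[which(v == 0)[1L]]
            if (is.null(nm)) nm <- which(v == 0)[1L]
            stop("cannot scale zero-variance column ", nm)
        }
    }
    pr <- stats::prcomp(x, center = center, scale. = scale)
    ve <- pr$sdev^2 / sum(pr$sdev^2)
    k <- if (is.null(nComponents)) ncol(pr$rotation)
         else min(nComponents, ncol(pr$rotation))
    scores <- pr$x[, seq_len(k), drop = FALSE]
    loadings <- pr$rotation[, seq_len(k), drop = FALSE]
    for (j in seq_len(k)) {
        i <- which.max(abs(loadings[, j]))
        if (loadings[i, j] < 0) {
            loadings[, j] <- -loadings[, j]
            scores[, j] <- -scores[, j]
        }
    }
    rownames(scores) <- rownames(x)
    new("PcaResult", scores = scores, loadings = loadings,
        varianceExplained = ve)
}

#' Individuals x CNVR segment-signal matrix
#'
#' Summarizes each individual's segment state over every CNV region, as
#' input for the structure PCA. Two encodings are available: `"indicator"`
#' gives +1 where the individual's overlapping segments are all gains, -1
#' where all losses, and 0 otherwise (no segment, a mixed segment, or
#' conflicting gain+loss evidence); `"log2"` gives the mean of the
#' overlapping segments' mean log2 ratios (0 where no segment overlaps).
#'
#' @param segments `GRanges` from [buildSegments()].
#' @param cnvrs `GRanges` from [mergeToCnvrs()] built from the same segments.
#' @param individuals full roster of individuals (rows); defaults to those
#'   with segments, but pass the whole cohort so non-carriers appear as zero
#'   rows.
#' @param encoding `"indicator"` or `"log2"`.
#' @return numeric matrix, individuals x regions (regions labelled
#'   `chrom:start-end`).
#' @export
segmentSignalMatrix <- function(segments, cnvrs,
                                individuals = unique(segments$individual),
                                encoding = c("indicator", "log2")) {
    encoding <- match.arg(encoding)
    out <- matrix(0, nrow = length(individuals), ncol = length(cnvrs),
                  dimnames = list(individuals,
                                  sprintf("%s:%d-%d", as.character(seqnames(cnvrs)),
                                          start(cnvrs), end(cnvrs))))
    if (!length(segments) || !length(cnvrs)) return(out)
    ov <- findOverlaps(segments, cnvrs, minoverlap = 1L)
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    rows <- match(segments$individual[q], individuals)
    keep <- !is.na(rows)
    q <- q[keep]; s <- s[keep]; rows <- rows[keep]
    cellKey <- paste(rows, s)
    if (encoding == "log2") {
        m <- tapply(segments$meanLog2Ratio[q], cellKey, mean)
    } else {
        m <- tapply(segments$state[q], cellKey, function(st) {
            if (all(st == "gain")) 1 else if (all(st == "loss")) -1 else 0
        })
    }
    ij <- do.call(rbind, strsplit(names(m), " "))
    out[cbind(as.integer(ij[, 1L]), as.integer(ij[, 2L]))] <- as.numeric(m)
    out
}
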