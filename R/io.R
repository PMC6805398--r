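#' @importFrom data.table fread fwrite as.data.table
NULL

# chromosome alias normalization: the horse literature mixes "ECA12" with
# BED-style "chr12"/"12"; internal naming is "chrN"
.normChrom <- function(x) {
    x <- as.character(x)
    x <- sub("^ECA", "chr", x)
    ifelse(grepl("^chr", x), x, paste0("chr", x))
}

#' Read a BED3/BED6 track
#'
#' BED files are 0-based half-open; the returned `GRanges` is 1-based
#' inclusive (the native GenomicRanges convention), so a BED record
#' `start=100 end=200` covers bases 101..200. `track`/`browser` and `#`
#' lines are skipped; malformed records (non-integer coordinates,
#' `start >= end`, fewer than 3 fields) raise an error naming the offending
#' line. Chromosome names are normalized to `chrN` (ECA aliases accepted).
#'
#' @param path BED file.
#' @param trackName name attached to the result (default: file base name).
#' @return `GRanges` with optional `name` and `score` metadata columns and a
#'   `metadata(x)$trackName`.
#' @export
readBed <- function(path, trackName = sub("\\.bed$", "", basename(path))) {
    lines <- readLines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
    lineNo <- which(keep)
    lines <- lines[keep]
    if (!length(lines)) {
        gr <- GRanges()
        metadata(gr)$trackName <- trackName
        return(gr)
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("BED line ", lineNo[which(nf < 3L)[1L]], ": fewer than 3 fields")
    chrom <- vapply(fields, `[[`, character(1), 1L)
    s <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
    e <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
    bad <- which(is.na(s) | is.na(e) | s != floor(s) | e != floor(e))
    if (length(bad))
        stop("BED line ", lineNo[bad[1L]], ": non-integer coordinates")
    bad <- which(s >= e | s < 0)
    if (length(bad))
        stop("BED line ", lineNo[bad[1L]], ": start must satisfy 0 <= start < end")
    gr <- GRanges(.normChrom(chrom), IRanges(s + 1, e))
    if (all(nf >= 4L)) gr$name <- vapply(fields, `[[`, character(1), 4L)
    if (all(nf >= 5L))
        gr$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 5L)))
    metadata(gr)$trackName <- trackName
    gr
}

#' Write a GRanges as BED
#'
#' Converts from 1-based inclusive to BED's 0-based half-open convention;
#' inverse of [readBed()].
#'
#' @param gr `GRanges`; `$name` and `$score` are written when present.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
    if (!length(gr)) { file.create(path); return(invisible(path)) }
    d <- data.frame(chrom = as.character(seqnames(gr)),
                    start = start(gr) - 1L, end = end(gr))
    if (!is.null(gr$name)) {
        d$name <- gr$name
        d$score <- if (!is.null(gr$score)) gr$score else 0
        d$strand <- "."
    }
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a chrom.sizes file
#'
#' @param path two-column TSV (chromosome, length in bp), no header.
#' @return named numeric vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
    d <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "size"))
    stats::setNames(d$size, .normChrom(d$chrom))
}

#' Read individual labels with a breed-to-cluster map
#'
#' @param path TSV with header and columns `individual`, `breed` (and
#'   optionally `cluster`).
#' @param clusterPath optional two-column TSV (`breed`, `cluster`) mapping
#'   breeds to ancestry clusters; when neither source provides clusters,
#'   each breed is its own cluster.
#' @return `data.frame(individual, breed, cluster)`.
#' @export
readLabels <- function(path, clusterPath = NULL) {
    d <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    stopifnot(all(c("individual", "breed") %in% names(d)))
    if (!"cluster" %in% names(d)) {
        if (!is.null(clusterPath)) {
            cm <- utils::read.table(clusterPath, sep = "\t", header = TRUE,
                                    stringsAsFactors = FALSE)
            d$cluster <- cm$cluster[match(d$breed, cm$breed)]
            if (anyNA(d$cluster))
                stop("breeds missing from cluster map: ",
                     paste(unique(d$breed[is.na(d$cluster)]), collapse = ", "))
        } else d$cluster <- d$breed
    }
    d[, c("individual", "breed", "cluster")]
}

#' @rdname readLabels
#' @param labels `data.frame(individual, breed, cluster)` to write.
#' @export
writeLabels <- function(labels, path) {
    utils::write.table(labels, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read/write an individuals x markers matrix as (gzipped) TSV
#'
#' On disk, rows are individuals (first column `individual`) and columns are
#' markers; in memory the matrix is markers x individuals to match the
#' cohort container.
#'
#' @param m markers x individuals numeric matrix with dimnames.
#' @param path `.tsv` or `.tsv.gz` path.
#' @return `readIntensityMatrix`: the markers x individuals matrix.
#' @export
writeIntensityMatrix <- function(m, path) {
    d <- data.table(individual = colnames(m))
    d <- cbind(d, as.data.table(t(m)))
    fwrite(d, path, sep = "\t")
    invisible(path)
}

#' @rdname writeIntensityMatrix
#' @export
readIntensityMatrix <- function(path) {
    # readLines decompresses .gz transparently, avoiding fread's optional
    # R.utils dependency
    d <- fread(text = readLines(path), sep = "\t", header = TRUE)
    ids <- d$individual
    m <- t(as.matrix(d[, -1]))
    colnames(m) <- ids
    m
}

#' Read/write SNP CNV call tables
#'
#' TSV with header, columns `individual`, `marker`, `chrom`, `pos` (1-based),
#' `state`, `log2Ratio`; the write/read pair is lossless for downstream use.
#'
#' @param calls call table from [callSnpCnvs()].
#' @param path TSV path.
#' @export
writeCalls <- function(calls, path) {
    fwrite(calls, path, sep = "\t")
    invisible(path)
}

#' @rdname writeCalls
#' @export
readCalls <- function(path) {
    as.data.frame(fread(path, sep = "\t", header = TRUE,
                        colClasses = list(character = c("individual", "marker",
                                                        "chrom", "state"))))
}

#' Write segments or CNV regions as TSV
#'
#' `format = "bed"` writes 0-based half-open coordinates (BED-compatible);
#' `format = "report"` writes 1-based inclusive coordinates with a header.
#'
#' @param gr segments from [buildSegments()] or regions from
#'   [mergeToCnvrs()].
#' @param path output path.
#' @param format `"bed"` or `"report"`.
#' @export
writeRegions <- function(gr, path, format = c("report", "bed")) {
    format <- match.arg(format)
    d <- as.data.frame(mcols(gr))
    if ("breedCarriers" %in% names(d)) {
        bc <- d$breedCarriers
        d$breedCarriers <- NULL
        colnames(bc) <- paste0("n_", colnames(bc))
        d <- cbind(d, as.data.frame(bc))
    }
    base <- data.frame(chrom = as.character(seqnames(gr)),
                       start = if (format == "bed") start(gr) - 1L else start(gr),
                       end = end(gr))
    utils::write.table(cbind(base, d), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = format == "report")
    invisible(path)
}

#' Read a gene-to-term annotation map
#'
#' @param path two-column TSV with header `gene`, `term`.
#' @return `data.frame(gene, term)` for [overrepresentation()].
#' @export
readTermMap <- function(path) {
    d <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
    stopifnot(all(c("gene", "term") %in% names(d)))
    d[, c("gene", "term")]
}

#' Write/read a complete cohort directory
#'
#' Persists a [CnvCohort-class] as plain text: `intensity.tsv.gz`,
#' `baf.tsv.gz`, `markers.tsv` (marker, chrom, pos), `labels.tsv` and
#' `chrom.sizes`.
#'
#' @param cohort a [CnvCohort-class].
#' @param dir directory (created if needed).
#' @return `readCohort`: the reconstructed [CnvCohort-class].
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeIntensityMatrix(intensity(cohort), file.path(dir, "intensity.tsv.gz"))
    writeIntensityMatrix(baf(cohort), file.path(dir, "baf.tsv.gz"))
    map <- markerMap(cohort)
    utils::write.table(
        data.frame(marker = names(map), chrom = as.character(seqnames(map)),
                   pos = start(map)),
        file.path(dir, "markers.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    writeLabels(sampleInfo(cohort), file.path(dir, "labels.tsv"))
    sl <- seqlengths(map)
    if (!anyNA(sl))
        utils::write.table(data.frame(names(sl), as.numeric(sl)),
                           file.path(dir, "chrom.sizes"), sep = "\t",
                           quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
    intens <- readIntensityMatrix(file.path(dir, "intensity.tsv.gz"))
    bafm <- readIntensityMatrix(file.path(dir, "baf.tsv.gz"))
    mk <- utils::read.table(file.path(dir, "markers.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
    map <- GRanges(.normChrom(mk$chrom), IRanges(mk$pos, width = 1L))
    names(map) <- mk$marker
    labels <- readLabels(file.path(dir, "labels.tsv"))
    csPath <- file.path(dir, "chrom.sizes")
    cs <- if (file.exists(csPath)) readChromSizes(csPath) else NULL
    CnvCohort(intens[names(map), , drop = FALSE],
              bafm[names(map), , drop = FALSE], map, labels, cs)
}
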