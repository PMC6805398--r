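#' Intersect CNV regions with an annotation track
#'
#' All (region, interval) pairs sharing at least 1 bp, with the shared
#' length. Bookended features (zero shared bases) do not intersect. The
#' operation is symmetric: swapping the inputs yields the same pair set.
#'
#' @param cnvrs `GRanges` of CNV regions.
#' @param track `GRanges` annotation track (e.g. from [readBed()]), with
#'   feature names in `track$name` if available.
#' @return `data.frame` with columns `regionIdx`, `trackIdx`, `chrom`,
#'   `regionStart`, `regionEnd`, `name`, `overlapBp`.
#' @export
intersectTrack <- function(cnvrs, track) {
    ov <- findOverlaps(cnvrs, track, minoverlap = 1L, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    olap <- width(pintersect(granges(cnvrs)[q], granges(track)[s],
                             ignore.strand = TRUE))
    nm <- if (!is.null(track$name)) track$name[s] else as.character(s)
    data.frame(regionIdx = q, trackIdx = s,
               chrom = as.character(seqnames(cnvrs))[q],
               regionStart = start(cnvrs)[q], regionEnd = end(cnvrs)[q],
               name = nm, overlapBp = olap)
}

#' Flag novel CNV regions against a published catalogue
#'
#' A region is novel iff it shares no >= 1 bp overlap with any catalogue
#' entry — the same overlap rule used to merge segments into CNVRs.
#'
#' @param cnvrs non-empty `GRanges` of CNV regions.
#' @param catalog `GRanges` of previously reported CNVRs.
#' @return a list: `novel` (logical per region), `nNovel`, `nRegions`,
#'   `pctNovel` (= 100 * nNovel / nRegions).
#' @export
flagNovel <- function(cnvrs, catalog) {
    if (!length(cnvrs)) stop("empty region set: novelty is undefined")
    novel <- countOverlaps(cnvrs, catalog, minoverlap = 1L,
                           ignore.strand = TRUE) == 0L
    list(novel = novel, nNovel = sum(novel), nRegions = length(cnvrs),
         pctNovel = 100 * sum(novel) / length(cnvrs))
}

#' Gene content of CNV regions
#'
#' Fraction of regions containing at least one gene (>= 1 bp overlap with
#' the gene track), per-region gene lists, and the deduplicated union gene
#' list. A gene spanning several regions appears once in the union and once
#' in each region's own list.
#'
#' @param cnvrs `GRanges` of CNV regions.
#' @param geneTrack `GRanges` with gene names in `$name`.
#' @return a list: `fractionWithGene` in `[0, 1]`, `genesPerRegion`
#'   (list of character vectors, one per region), `geneUnion` (character).
#' @export
geneContentSummary <- function(cnvrs, geneTrack) {
    hits <- intersectTrack(cnvrs, geneTrack)
    per <- vector("list", length(cnvrs))
    for (i in seq_along(per)) per[[i]] <- character()
    if (nrow(hits)) {
        sp <- split(hits$name, hits$regionIdx)
        per[as.integer(names(sp))] <- lapply(sp, function(x) unique(x))
    }
    withGene <- lengths(per) > 0L
    list(fractionWithGene = if (length(cnvrs)) mean(withGene) else 0,
         genesPerRegion = per,
         geneUnion = unique(unlist(per)))
}

#' Hypergeometric term overrepresentation test
#'
#' For each annotation term, the one-sided hypergeometric tail probabilities
#' of seeing at least (overrepresentation) or at most (underrepresentation)
#' the observed number of list genes carrying the term, given the universe.
#' The reported `p` is the smaller tail with its direction; Bonferroni
#' (`min(1, p x nTerms)`) and Benjamini-Hochberg FDR are reported alongside,
#' so both "Bonferroni P < 0.05" and FDR-style readings are available.
#'
#' @param geneList character, genes of interest; must be a subset of
#'   `universe`.
#' @param universe character, all assayable genes.
#' @param termMap `data.frame(gene, term)`; every term must annotate at
#'   least one universe gene.
#' @return `data.frame` sorted by `p`: `term`, `listHits`, `universeHits`,
#'   `listSize`, `universeSize`, `pOver`, `pUnder`, `p`, `direction`,
#'   `bonferroniP`, `bhFdrQ`.
#' @examples
#' uni <- paste0("g", 1:20)
#' tm <- data.frame(gene = uni[1:5], term = "T1")
#' overrepresentation(uni[1:5], uni, tm)   # p = 1 / choose(20, 5)
#' @export
overrepresentation <- function(geneList, universe, termMap) {
    universe <- unique(universe)
    geneList <- unique(geneList)
    missing <- setdiff(geneList, universe)
    if (length(missing))
        stop("list genes absent from universe: ",
             paste(utils::head(missing, 3), collapse = ", "))
    termMap <- termMap[termMap$gene %in% universe, , drop = FALSE]
    terms <- unique(as.character(termMap$term))
    if (!length(terms)) stop("no term annotates any universe gene")
    N <- length(universe); n <- length(geneList)
    res <- do.call(rbind, lapply(terms, function(tm) {
        genes <- unique(termMap$gene[termMap$term == tm])
        m <- length(genes)
        k <- length(intersect(genes, geneList))
        pOver <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
        pUnder <- stats::phyper(k, m, N - m, n)
        data.frame(term = tm, listHits = k, universeHits = m,
                   listSize = n, universeSize = N,
                   pOver = pOver, pUnder = pUnder,
                   p = min(pOver, pUnder),
                   direction = if (pOver <= pUnder) "over" else "under")
    }))
    res$bonferroniP <- pmin(1, res$p * length(terms))
    res$bhFdrQ <- stats::p.adjust(res$p, method = "BH")
    res <- res[order(res$p), ]
    rownames(res) <- NULL
    res
}
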