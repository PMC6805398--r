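#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. The cohort comes from
#' exactly one of three sources, checked in this order: an in-memory
#' [CnvCohort-class] (`cohort`), a [simConfig()] to simulate from
#' (`simConfig`), or a cohort directory written by [writeCohort()]
#' (`cohortDir`).
#'
#' @param cohort,simConfig,cohortDir cohort source (exactly one non-`NULL`).
#' @param referenceBreed breed defining the reference profile.
#' @param gainThreshold,lossThreshold log2-ratio call thresholds
#'   ([callSnpCnvs()]).
#' @param minMarkers,maxGapMarkers segmentation rules ([buildSegments()]).
#' @param minFraction within-group frequency filter ([positionFrequency()]).
#' @param highlightThreshold carrier-percentage highlight cutoff
#'   ([privateChromosomeProfile()]).
#' @param exclude individual ids excluded before calling (QC failures are an
#'   input, not recomputed).
#' @param tracks named list of optional annotation inputs: `genes`, `qtl`,
#'   `knownCnvrs` (`GRanges` or BED paths) and `termMap` (`data.frame` or
#'   TSV path).
#' @param nPcaComponents components retained in the two PCAs.
#' @param seed seed for any stochastic stage (simulation).
#' @param outDir optional output directory; when given, every stage result
#'   is written as TSV/BED plus a `run.log`.
#' @return a validated `PipelineConfig` list.
#' @export
pipelineConfig <- function(cohort = NULL, simConfig = NULL, cohortDir = NULL,
                           referenceBreed = "BelgianDraught",
                           gainThreshold = 0.3, lossThreshold = 0.3,
                           minMarkers = 3L, maxGapMarkers = 0L,
                           minFraction = 0.01, highlightThreshold = 20,
                           exclude = character(), tracks = list(),
                           nPcaComponents = 10L, seed = 1L, outDir = NULL) {
    if (is.null(cohort) && is.null(simConfig) && is.null(cohortDir))
        stop("one of cohort, simConfig, cohortDir must be supplied")
    stopifnot(gainThreshold > 0, lossThreshold > 0, minMarkers >= 1,
              maxGapMarkers >= 0, minFraction > 0, minFraction <= 1)
    for (p in c("genes", "qtl", "knownCnvrs", "termMap"))
        if (!is.null(tracks[[p]]) && is.character(tracks[[p]]) &&
            !file.exists(tracks[[p]]))
            stop("track file does not exist: ", tracks[[p]])
    if (!is.null(cohortDir) && !dir.exists(cohortDir))
        stop("cohort directory does not exist: ", cohortDir)
    structure(list(cohort = cohort, simConfig = simConfig,
                   cohortDir = cohortDir, referenceBreed = referenceBreed,
                   gainThreshold = gainThreshold, lossThreshold = lossThreshold,
                   minMarkers = as.integer(minMarkers),
                   maxGapMarkers = as.integer(maxGapMarkers),
                   minFraction = minFraction,
                   highlightThreshold = highlightThreshold,
                   exclude = exclude, tracks = tracks,
                   nPcaComponents = as.integer(nPcaComponents),
                   seed = as.integer(seed), outDir = outDir),
              class = "PipelineConfig")
}

.loadTrack <- function(x) if (is.character(x)) readBed(x) else x
.loadTermMap <- function(x) if (is.character(x)) readTermMap(x) else x

#' Run the full CNV diversity pipeline
#'
#' Executes calling, segmentation, CNVR construction, breed/cluster sharing
#' analysis, structure PCA and (when tracks are configured) annotation and
#' enrichment, in dependency order; any stage failure aborts with the stage
#' name. Given the same configuration and seed the result bundle is
#' deterministic.
#'
#' @param config a [pipelineConfig()].
#' @return (invisibly) a named list with elements `cohort`, `truth` (when
#'   simulated), `profile`, `calls`, `segments`, `segmentTable`, `cnvrs`,
#'   `coverage`, `segmentShare`, `breedFrequency`, `clusterFrequency`,
#'   `breedPrivate`, `clusterPrivate`, `breedProfile`, `clusterProfile`,
#'   `bafPca`, `segmentPca`, and `annotation` (itself a list) plus
#'   `chromSizes`.
#' @examples
#' cfg <- pipelineConfig(simConfig = simConfig(seed = 11))
#' res <- runPipeline(cfg)
#' res$cnvrs
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }
    set.seed(config$seed)
    res <- list()
    res$truth <- NULL
    cohort <- if (!is.null(config$cohort)) config$cohort
        else if (!is.null(config$simConfig)) {
            sim <- stage("simulate", simulateCohort(config$simConfig))
            res$truth <- sim$truth
            sim$cohort
        } else stage("load", readCohort(config$cohortDir))
    res$cohort <- cohort
    info <- sampleInfo(cohort)
    sl <- seqlengths(markerMap(cohort))
    chromSizes <- if (!anyNA(sl) && length(sl)) stats::setNames(as.numeric(sl), names(sl))
        else stop("cohort carries no chromosome sizes")
    res$chromSizes <- chromSizes

    res$profile <- stage("reference",
        buildReferenceProfile(cohort, config$referenceBreed))
    res$calls <- stage("calling",
        callSnpCnvs(cohort, res$profile, config$gainThreshold,
                    config$lossThreshold, exclude = config$exclude))
    res$segments <- stage("segmentation",
        buildSegments(res$calls, markerMap(cohort), config$minMarkers,
                      config$maxGapMarkers))
    res$segmentTable <- stage("segment summary",
        segmentSummary(res$segments, info, chromSizes))
    res$cnvrs <- stage("cnvr", mergeToCnvrs(res$segments, info))
    res$coverage <- stage("coverage",
        chromosomeCoverage(res$segments, chromSizes, info$individual))
    res$segmentShare <- if (length(res$segments))
        stage("segment share", chromosomeSegmentShare(res$segments)) else NULL

    res$breedFrequency <- stage("breed frequency",
        positionFrequency(res$calls, info, "breed", config$minFraction))
    res$clusterFrequency <- stage("cluster frequency",
        positionFrequency(res$calls, info, "cluster", config$minFraction))
    res$breedPrivate <- stage("breed private", uniquePrivate(res$breedFrequency))
    res$clusterPrivate <- stage("cluster private",
        uniquePrivate(res$clusterFrequency))
    res$breedProfile <- stage("breed profile",
        privateChromosomeProfile(res$breedPrivate, config$highlightThreshold))
    res$clusterProfile <- stage("cluster profile",
        privateChromosomeProfile(res$clusterPrivate, config$highlightThreshold))

    res$bafPca <- stage("BAF PCA",
        runPca(t(baf(cohort)), nComponents = config$nPcaComponents))
    segMat <- stage("segment matrix",
        segmentSignalMatrix(res$segments, res$cnvrs, info$individual))
    res$segmentPca <- if (ncol(segMat) >= 2L)
        stage("segment PCA", runPca(segMat, nComponents = config$nPcaComponents))
        else NULL

    tr <- config$tracks
    ann <- list()
    if (!is.null(tr$genes)) {
        genes <- .loadTrack(tr$genes)
        ann$geneOverlaps <- stage("gene overlap", intersectTrack(res$cnvrs, genes))
        ann$geneContent <- stage("gene content",
            geneContentSummary(res$cnvrs, genes))
        if (!is.null(tr$termMap)) {
            tm <- .loadTermMap(tr$termMap)
            universe <- unique(genes$name)
            ann$enrichment <- stage("enrichment",
                overrepresentation(ann$geneContent$geneUnion, universe, tm))
        }
    }
    if (!is.null(tr$qtl))
        ann$qtlOverlaps <- stage("qtl overlap",
            intersectTrack(res$cnvrs, .loadTrack(tr$qtl)))
    if (!is.null(tr$knownCnvrs))
        ann$novelty <- stage("novelty",
            flagNovel(res$cnvrs, .loadTrack(tr$knownCnvrs)))
    res$annotation <- ann

    if (!is.null(config$outDir)) stage("write outputs", .writeBundle(res, config))
    invisible(res)
}

.writeBundle <- function(res, config) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$outDir, f)
    writeCalls(res$calls, out("snp_cnv_calls.tsv"))
    writeRegions(res$segments, out("segments.tsv"), "report")
    writeRegions(res$segments, out("segments.bed"), "bed")
    writeRegions(res$cnvrs, out("cnvrs.tsv"), "report")
    utils::write.table(res$segmentTable, out("segment_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$coverage, out("chromosome_coverage.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (lvl in c("breed", "cluster")) {
        fr <- res[[paste0(lvl, "Frequency")]]
        utils::write.table(fr[fr$retained, ],
                           out(sprintf("%s_frequency.tsv", lvl)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(res[[paste0(lvl, "Private")]]$report,
                           out(sprintf("%s_private_report.tsv", lvl)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        hl <- res[[paste0(lvl, "Profile")]]$highlight
        if (nrow(hl)) {
            gr <- GRanges(hl$chrom, IRanges(hl$pos, width = 1L))
            gr$name <- paste(hl$group, hl$state, sep = "_")
            gr$score <- hl$carrierPct
            writeBed(gr, out(sprintf("%s_private_highlights.bed", lvl)))
        }
    }
    utils::write.table(data.frame(individual = rownames(pcaScores(res$bafPca)),
                                  pcaScores(res$bafPca)),
                       out("baf_pca_scores.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    # run log: enough to reproduce the run byte for byte
    cfgFile <- out("pipeline_config.yaml")
    cfgDump <- config[!vapply(config, is.object, logical(1))]
    cfgDump$cohort <- NULL
    yaml::write_yaml(lapply(cfgDump, function(x) if (is.null(x)) NA else x),
                     cfgFile)
    writeLines(c(
        sprintf("cnvDiversity %s",
                as.character(utils::packageVersion("cnvDiversity"))),
        sprintf("run at: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
        sprintf("seed: %d", config$seed),
        sprintf("config md5: %s", unname(tools::md5sum(cfgFile)))),
        out("run.log"))
    invisible(NULL)
}
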