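#' Default breed layout for the synthetic cohort
#'
#' Eight European breeds in three ancestry clusters (Draught, Warmblood,
#' Friesian), with cohort sizes scaled to a desk-size total of ~600
#' individuals while preserving the relative sizes of the emulated study
#' design. The Belgian draught is the designated reference breed: large
#' sample, lowest signal variance, kept CNV-quiet by the default planted set.
#'
#' @return `data.frame` with columns `name`, `n`, `cluster`.
#' @export
defaultBreedTable <- function() {
    data.frame(
        name = c("Ardenner", "BelgianDraught", "GermanDraught", "ExmoorPony",
                 "VlaamsPaard", "BelgianWarmblood", "SwedishWarmblood",
                 "Friesian"),
        n = c(8L, 103L, 8L, 88L, 8L, 164L, 131L, 91L),
        cluster = c("Draught", "Draught", "Draught", "Draught", "Draught",
                    "Warmblood", "Warmblood", "Friesian"))
}

#' Describe one planted CNV region
#'
#' @param chrom chromosome name (matching the simulated map, e.g. `"chr3"`).
#' @param start,end 1-based inclusive bp span; must cover enough markers to
#'   survive the segmentation minimum (>= 3 at default settings).
#' @param copyNumber integer >= 0 and != 2 (diploid baseline is 2).
#' @param carrierGroups character, breed and/or cluster names that carry the
#'   variant.
#' @param carrierFrequency fraction in (0, 1]; carriers are drawn binomially
#'   at this rate within each carrier group.
#' @param id optional region id; autogenerated when `NULL`.
#' @return a one-row `data.frame` understood by [simConfig()].
#' @export
plantedCnvr <- function(chrom, start, end, copyNumber, carrierGroups,
                        carrierFrequency, id = NULL) {
    stopifnot(start <= end, copyNumber >= 0, copyNumber != 2,
              all(carrierFrequency > 0), all(carrierFrequency <= 1))
    if (is.null(id))
        id <- sprintf("%s_%d_%d_cn%d", chrom, start, end, copyNumber)
    data.frame(id = id, chrom = chrom, start = start, end = end,
               copyNumber = as.integer(copyNumber),
               group = carrierGroups,
               frequency = rep(carrierFrequency, length.out = length(carrierGroups)))
}

#' Default planted CNV region set
#'
#' Mirrors the structure the analysis is designed to resolve: CNVRs shared
#' across breeds, breed-private CNVRs (a Friesian gain and an Exmoor loss,
#' echoing the private gains/losses the field reports for those breeds) and
#' three cluster-private CNVRs per ancestry cluster. Frequencies involving
#' the reference breed are capped at 0.3 so that planted carriers inflate the
#' reference profile by at most a factor 1.15, keeping carrier/non-carrier
#' log2 ratios on opposite sides of the default +/-0.3 call thresholds.
#'
#' @return `data.frame` of planted regions (one row per region x carrier group).
#' @export
defaultPlantedCnvrs <- function() {
    nonRef <- setdiff(defaultBreedTable()$name, "BelgianDraught")
    rbind(
        plantedCnvr("chr1", 10000001L, 11000000L, 3L, nonRef, 0.3, id = "shared_gain_1"),
        plantedCnvr("chr2", 30000001L, 31000000L, 1L, nonRef, 0.3, id = "shared_loss_1"),
        plantedCnvr("chr3",  5000001L,  6000000L, 3L, "Friesian",   0.3, id = "fri_private_gain"),
        plantedCnvr("chr4", 20000001L, 21000000L, 1L, "ExmoorPony", 0.3, id = "exm_private_loss"),
        plantedCnvr("chr5", 10000001L, 11000000L, 3L, "Warmblood", 0.5, id = "wb_cluster_gain_1"),
        plantedCnvr("chr5", 40000001L, 41000000L, 1L, "Warmblood", 0.5, id = "wb_cluster_loss_1"),
        plantedCnvr("chr6", 25000001L, 26000000L, 3L, "Warmblood", 0.5, id = "wb_cluster_gain_2"),
        plantedCnvr("chr7", 10000001L, 11000000L, 3L, "Friesian",  0.5, id = "fri_cluster_gain_1"),
        plantedCnvr("chr7", 40000001L, 41000000L, 3L, "Friesian",  0.5, id = "fri_cluster_gain_2"),
        plantedCnvr("chr8", 25000001L, 26000000L, 1L, "Friesian",  0.5, id = "fri_cluster_loss_1"),
        plantedCnvr("chr9", 10000001L, 11000000L, 1L, "Draught",   0.25, id = "dr_cluster_loss_1"),
        plantedCnvr("chr9", 40000001L, 41000000L, 3L, "Draught",   0.25, id = "dr_cluster_gain_1"),
        plantedCnvr("chr10", 25000001L, 26000000L, 1L, "Draught",  0.25, id = "dr_cluster_loss_2"))
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic cohort generator. The
#' defaults define the emulated study: 8 breeds / 3 clusters / ~600
#' individuals, 10 autosomes of 50 Mb carrying 500 uniformly spaced markers
#' each (5,000 markers), per-marker log2 intensity noise of sd 0.05 and BAF
#' noise of sd 0.03, with the reference breed's intensity noise halved to
#' reproduce its role as the lowest-variance breed.
#'
#' @param seed integer; one global seed drives a single RNG stream, so a
#'   fixed seed yields bit-identical output.
#' @param nAutosomes,chromLengthBp,nMarkersPerChrom genome/marker layout.
#' @param breeds `data.frame(name, n, cluster)` as [defaultBreedTable()].
#' @param referenceBreed breed whose mean signal defines the reference.
#' @param plantedCnvrs `data.frame` from [plantedCnvr()] rows (or `NULL` for
#'   a CNV-free cohort).
#' @param noiseSd sd of per-marker log2 intensity noise.
#' @param bafNoiseSd sd of truncated BAF noise.
#' @param referenceNoiseFactor multiplier on `noiseSd` for reference-breed
#'   individuals (the study breed was chosen for its low variance; the true
#'   value is unknown, so it is a parameter).
#' @param markerSpacing `"uniform"` (analytic coverage expectations) or
#'   `"random"` (sorted uniform draws).
#' @param baselineIntensity centre of the per-marker diploid baseline.
#' @param clusterFst,breedFst Balding-Nichols drift of cluster- and
#'   breed-level allele frequencies away from the ancestral frequency; these
#'   give the BAF matrix its breed-separating structure.
#' @return a validated `SimConfig` list.
#' @export
simConfig <- function(seed = 1L, nAutosomes = 10L, chromLengthBp = 5e7,
                      nMarkersPerChrom = 500L, breeds = defaultBreedTable(),
                      referenceBreed = "BelgianDraught",
                      plantedCnvrs = defaultPlantedCnvrs(),
                      noiseSd = 0.05, bafNoiseSd = 0.03,
                      referenceNoiseFactor = 0.5,
                      markerSpacing = c("uniform", "random"),
                      baselineIntensity = 2, clusterFst = 0.1,
                      breedFst = 0.05) {
    markerSpacing <- match.arg(markerSpacing)
    stopifnot(is.data.frame(breeds),
              all(c("name", "n", "cluster") %in% names(breeds)),
              all(breeds$n >= 1), !anyDuplicated(breeds$name),
              nAutosomes >= 1, nMarkersPerChrom >= 1, chromLengthBp >= nMarkersPerChrom,
              noiseSd >= 0, bafNoiseSd >= 0, referenceNoiseFactor >= 0,
              baselineIntensity > 0)
    if (!referenceBreed %in% breeds$name)
        stop("referenceBreed ", sQuote(referenceBreed), " is not a configured breed")
    groups <- c(breeds$name, unique(breeds$cluster))
    if (!is.null(plantedCnvrs) && nrow(plantedCnvrs)) {
        bad <- setdiff(plantedCnvrs$group, groups)
        if (length(bad))
            stop("planted carrier groups not among breeds/clusters: ",
                 paste(bad, collapse = ", "))
        chroms <- sprintf("chr%d", seq_len(nAutosomes))
        if (!all(plantedCnvrs$chrom %in% chroms))
            stop("planted CNVR chromosome outside the simulated genome")
        if (any(plantedCnvrs$end > chromLengthBp))
            stop("planted CNVR extends beyond chromosome end")
        .checkPlantedConflicts(plantedCnvrs)
    }
    structure(list(seed = as.integer(seed), nAutosomes = as.integer(nAutosomes),
                   chromLengthBp = chromLengthBp,
                   nMarkersPerChrom = as.integer(nMarkersPerChrom),
                   breeds = breeds, referenceBreed = referenceBreed,
                   plantedCnvrs = plantedCnvrs, noiseSd = noiseSd,
                   bafNoiseSd = bafNoiseSd,
                   referenceNoiseFactor = referenceNoiseFactor,
                   markerSpacing = markerSpacing,
                   baselineIntensity = baselineIntensity,
                   clusterFst = clusterFst, breedFst = breedFst),
              class = "SimConfig")
}

# distinct regions overlapping on one chromosome must agree on copy number
.checkPlantedConflicts <- function(p) {
    reg <- unique(p[, c("id", "chrom", "start", "end", "copyNumber")])
    bychr <- split(reg, reg$chrom)
    for (r in bychr) {
        if (nrow(r) < 2) next
        for (i in seq_len(nrow(r) - 1)) for (j in seq(i + 1, nrow(r))) {
            if (r$start[i] <= r$end[j] && r$start[j] <= r$end[i] &&
                r$copyNumber[i] != r$copyNumber[j])
                stop("planted CNVRs ", r$id[i], " and ", r$id[j],
                     " overlap with conflicting copy numbers")
        }
    }
    invisible(TRUE)
}

#' Read a simulation configuration from YAML
#'
#' The YAML mirrors [simConfig()] arguments; `breeds` is a list of
#' `{name, n, cluster}` records and `plantedCnvrs` a list of
#' `{chrom, start, end, copyNumber, carrierGroups, carrierFrequency}` records.
#'
#' @param path YAML file path.
#' @return a validated `SimConfig`.
#' @export
readSimConfig <- function(path) {
    y <- yaml::read_yaml(path)
    if (!is.null(y$breeds))
        y$breeds <- do.call(rbind, lapply(y$breeds, function(b)
            data.frame(name = b$name, n = as.integer(b$n), cluster = b$cluster)))
    if (!is.null(y$plantedCnvrs))
        y$plantedCnvrs <- do.call(rbind, lapply(y$plantedCnvrs, function(p)
            plantedCnvr(p$chrom, p$start, p$end, p$copyNumber,
                        unlist(p$carrierGroups), unlist(p$carrierFrequency),
                        id = p$id)))
    do.call(simConfig, y)
}

#' Generate a synthetic multi-breed cohort with planted CNV regions
#'
#' Produces marker intensities and B-allele frequencies for every individual,
#' plus a truth table of planted carrier status. Intensities follow
#' `baseline * (copy / 2) * exp(Normal(0, noiseSd * ln 2))`, so log2 ratios
#' against a clean reference are Normal around `log2(copy / 2)`; homozygous
#' deletions retain a background-signal floor of 0.05 x baseline so that
#' intensities stay positive. BAF is drawn from the genotype at the
#' individual's local copy number (clusters {0, 1/2, 1} when diploid, pushed
#' toward {0, 1} in hemizygous deletions, {0, 1/3, 2/3, 1} in single-copy
#' gains) under hierarchically drifted breed allele frequencies, then
#' perturbed by truncated Gaussian noise.
#'
#' @param config a [simConfig()] object.
#' @return a list with elements
#'   \describe{
#'     \item{cohort}{a [CnvCohort-class] (per-marker baseline intensities in
#'       `metadata(cohort)$baseline`).}
#'     \item{truth}{a list: `regions` (one row per planted region x carrier
#'       group, with realized carrier counts) and `carriers` (one row per
#'       individual of each carrier group with a logical `carrier` flag).}
#'     \item{chromSizes}{named chromosome lengths.}
#'   }
#' @examples
#' sim <- simulateCohort(simConfig(seed = 7))
#' sim$cohort
#' head(sim$truth$regions)
#' @export
simulateCohort <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed)
    chroms <- sprintf("chr%d", seq_len(config$nAutosomes))
    nm <- config$nMarkersPerChrom
    L <- config$chromLengthBp

    pos <- lapply(chroms, function(ch) {
        if (config$markerSpacing == "uniform")
            round((seq_len(nm) - 0.5) * L / nm)
        else sort(sample.int(L, nm))
    })
    map <- GRanges(rep(chroms, each = nm),
                   IRanges(unlist(pos), width = 1L))
    names(map) <- sprintf("mk_%s_%04d", rep(chroms, each = nm),
                          rep(seq_len(nm), length(chroms)))
    chromSizes <- stats::setNames(rep(L, length(chroms)), chroms)
    seqlengths(map) <- chromSizes

    breeds <- config$breeds
    labels <- data.frame(
        individual = sprintf("%s_%03d", rep(breeds$name, breeds$n),
                             unlist(lapply(breeds$n, seq_len))),
        breed = rep(breeds$name, breeds$n),
        cluster = rep(breeds$cluster, breeds$n))
    M <- length(map); N <- nrow(labels)

    # per-marker diploid baseline shared by all individuals
    baseline <- config$baselineIntensity * exp(stats::rnorm(M, 0, 0.15 * log(2)))

    # copy-number matrix from planted regions (binomial carrier draw per group)
    cn <- matrix(2L, nrow = M, ncol = N,
                 dimnames = list(names(map), labels$individual))
    truthRegions <- NULL; truthCarriers <- NULL
    planted <- config$plantedCnvrs
    if (!is.null(planted) && nrow(planted)) {
        for (k in seq_len(nrow(planted))) {
            p <- planted[k, ]
            members <- if (p$group %in% breeds$name)
                which(labels$breed == p$group)
            else which(labels$cluster == p$group)
            if (p$frequency * length(members) < 1)
                warning("planted region ", p$id, " in group ", p$group,
                        ": expected carrier count below 1; region may be empty")
            carrier <- stats::rbinom(length(members), 1L, p$frequency) == 1L
            mk <- which(as.character(seqnames(map)) == p$chrom &
                        start(map) >= p$start & start(map) <= p$end)
            if (length(mk) && any(carrier))
                cn[mk, members[carrier]] <- p$copyNumber
            truthRegions <- rbind(truthRegions, data.frame(
                id = p$id, chrom = p$chrom, start = p$start, end = p$end,
                copyNumber = p$copyNumber, group = p$group,
                frequency = p$frequency, nMembers = length(members),
                nCarriers = sum(carrier), nMarkers = length(mk)))
            truthCarriers <- rbind(truthCarriers, data.frame(
                individual = labels$individual[members], id = p$id,
                group = p$group, carrier = carrier))
        }
    }

    # intensity: baseline x copy-scaling x lognormal noise (reference breed
    # gets reduced noise, emulating its role as the low-variance breed)
    sdvec <- rep(config$noiseSd, N)
    sdvec[labels$breed == config$referenceBreed] <-
        config$noiseSd * config$referenceNoiseFactor
    eps <- matrix(stats::rnorm(M * N, 0, rep(sdvec, each = M) * log(2)), M, N)
    copyFactor <- pmax(cn, 0.1) / 2
    intens <- baseline * copyFactor * exp(eps)
    dimnames(intens) <- dimnames(cn)

    # hierarchical allele frequencies: ancestral -> cluster -> breed
    p0 <- stats::runif(M, 0.05, 0.95)
    bnDraw <- function(p, fst) {
        if (fst <= 0) return(p)
        a <- p * (1 - fst) / fst; b <- (1 - p) * (1 - fst) / fst
        pmin(0.999, pmax(0.001, stats::rbeta(length(p), a, b)))
    }
    clusters <- unique(breeds$cluster)
    pClust <- vapply(clusters, function(cl) bnDraw(p0, config$clusterFst),
                     numeric(M))
    colnames(pClust) <- clusters
    pBreed <- vapply(seq_len(nrow(breeds)), function(i)
        bnDraw(pClust[, breeds$cluster[i]], config$breedFst), numeric(M))
    colnames(pBreed) <- breeds$name

    bafClean <- matrix(0, M, N, dimnames = dimnames(cn))
    for (b in breeds$name) {
        cols <- which(labels$breed == b)
        g <- matrix(stats::rbinom(M * length(cols), 2L, rep(pBreed[, b], length(cols))),
                    M, length(cols))
        bafClean[, cols] <- g / 2
    }
    # re-draw BAF where the local copy number is not diploid
    odd <- which(cn != 2L)
    if (length(odd)) {
        mkIdx <- (odd - 1L) %% M + 1L
        colIdx <- (odd - 1L) %/% M + 1L
        p <- pBreed[cbind(mkIdx, match(labels$breed[colIdx], breeds$name))]
        cnv <- cn[odd]
        v <- numeric(length(odd))
        v[cnv == 0L] <- 0.5
        h <- cnv >= 1L
        if (any(h)) v[h] <- stats::rbinom(sum(h), cnv[h], p[h]) / cnv[h]
        bafClean[odd] <- v
    }
    bafNoise <- matrix(stats::rnorm(M * N, 0, config$bafNoiseSd), M, N)
    bafMat <- pmin(pmax(bafClean + bafNoise, 0), 1)

    cohort <- CnvCohort(intens, bafMat, map, labels, chromSizes)
    metadata(cohort)$baseline <- baseline
    metadata(cohort)$seed <- config$seed
    list(cohort = cohort,
         truth = list(regions = truthRegions, carriers = truthCarriers),
         chromSizes = chromSizes)
}

#' Write the planted-region truth table as BED6
#'
#' One record per planted CNV region per carrier group, 0-based half-open;
#' the name encodes region id, copy number and carrier group, the score the
#' realized carrier percentage within the group.
#'
#' @param truth the `truth` element returned by [simulateCohort()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTruthBed <- function(truth, path) {
    reg <- truth$regions
    if (is.null(reg) || !nrow(reg)) {
        file.create(path)
        return(invisible(path))
    }
    bed <- data.frame(chrom = reg$chrom, start = reg$start - 1L, end = reg$end,
                      name = sprintf("%s|cn%d|%s", reg$id, reg$copyNumber, reg$group),
                      score = round(100 * reg$nCarriers / reg$nMembers, 1),
                      strand = ".")
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
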