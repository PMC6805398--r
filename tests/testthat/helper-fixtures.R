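# Small fixtures built in code.

# hand-built cohort: intensities specified directly, flat BAF
makeTinyCohort <- function(intens, breeds, positions = NULL,
                           chrom = "chr1", chromLen = 1e6) {
    M <- nrow(intens); N <- ncol(intens)
    if (is.null(positions)) positions <- seq_len(M) * 100L
    if (is.null(rownames(intens)))
        rownames(intens) <- sprintf("m%02d", seq_len(M))
    if (is.null(colnames(intens)))
        colnames(intens) <- sprintf("i%02d", seq_len(N))
    map <- GenomicRanges::GRanges(chrom, IRanges::IRanges(positions, width = 1L))
    names(map) <- rownames(intens)
    labels <- data.frame(individual = colnames(intens), breed = breeds,
                         cluster = breeds)
    bafm <- matrix(0.5, M, N, dimnames = dimnames(intens))
    CnvCohort(intens, bafm, map, labels,
              stats::setNames(chromLen, chrom))
}

# random call table over a marker map of `nChrom` x `nPerChrom` markers
randomCalls <- function(nCalls = 80, nInd = 6, nChrom = 2, nPerChrom = 30) {
    chroms <- sprintf("chr%d", seq_len(nChrom))
    map <- GenomicRanges::GRanges(rep(chroms, each = nPerChrom),
        IRanges::IRanges(rep(seq_len(nPerChrom) * 1000L, nChrom), width = 1L))
    names(map) <- sprintf("mk_%s_%02d", rep(chroms, each = nPerChrom),
                          rep(seq_len(nPerChrom), nChrom))
    pick <- sort(sample(length(map) * nInd, min(nCalls, length(map) * nInd)))
    mi <- (pick - 1L) %% length(map) + 1L
    ii <- (pick - 1L) %/% length(map) + 1L
    calls <- data.frame(
        individual = sprintf("i%02d", ii),
        marker = names(map)[mi],
        chrom = as.character(GenomicRanges::seqnames(map))[mi],
        pos = GenomicRanges::start(map)[mi],
        state = sample(c("gain", "loss"), length(pick), replace = TRUE),
        log2Ratio = stats::rnorm(length(pick), 0, 1))
    list(calls = calls, map = map)
}

# random segment table (data.frame and GRanges views)
randomSegments <- function(n = 30, nChrom = 2, span = 1e5) {
    chrom <- sprintf("chr%d", sample.int(nChrom, n, replace = TRUE))
    start <- sample.int(span, n, replace = TRUE)
    width <- sample.int(round(span / 6), n, replace = TRUE)
    df <- data.frame(chrom = chrom, start = start, end = start + width,
                     individual = sprintf("i%02d", sample.int(8, n, TRUE)),
                     state = sample(c("gain", "loss", "mixed"), n, TRUE,
                                    prob = c(0.5, 0.4, 0.1)))
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start, df$end))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        individual = df$individual, state = df$state,
        nMarkers = rep(3L, n), meanLog2Ratio = stats::rnorm(n))
    list(df = df, gr = gr)
}

randomTrack <- function(n = 15, nChrom = 2, span = 1e5, prefix = "f") {
    chrom <- sprintf("chr%d", sample.int(nChrom, n, replace = TRUE))
    start <- sample.int(span, n, replace = TRUE)
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start, start + sample.int(round(span / 5), n, TRUE)))
    gr$name <- sprintf("%s%02d", prefix, seq_len(n))
    gr
}

# a small simulated cohort shared by several test files (lazy, cached)
.smallSimCache <- new.env()
smallSim <- function() {
    if (is.null(.smallSimCache$sim)) {
        breeds <- data.frame(
            name = c("Ref", "A", "B", "C"),
            n = c(30L, 40L, 40L, 40L),
            cluster = c("c1", "c1", "c2", "c3"))
        planted <- rbind(
            plantedCnvr("chr1", 200001, 400000, 3L, "A", 0.4, id = "gainA"),
            plantedCnvr("chr2", 500001, 700000, 1L, "B", 0.4, id = "lossB"),
            plantedCnvr("chr2", 100001, 300000, 3L, c("A", "B", "C"), 0.5,
                        id = "sharedGain"))
        cfg <- simConfig(seed = 99, nAutosomes = 2, chromLengthBp = 1e6,
                         nMarkersPerChrom = 50, breeds = breeds,
                         referenceBreed = "Ref", plantedCnvrs = planted,
                         noiseSd = 0.05)
        .smallSimCache$sim <- simulateCohort(cfg)
        .smallSimCache$cfg <- cfg
    }
    list(sim = .smallSimCache$sim, cfg = .smallSimCache$cfg)
}
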