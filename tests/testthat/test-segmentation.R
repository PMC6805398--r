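mkMap <- function(n = 10, chrom = "chr1", spacing = 100L) {
    map <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(seq_len(n) * spacing, width = 1L))
    names(map) <- sprintf("m%02d", seq_len(n))
    map
}

mkCalls <- function(map, markers, states, individual = "i1") {
    i <- match(markers, names(map))
    data.frame(individual = individual, marker = markers,
               chrom = as.character(GenomicRanges::seqnames(map))[i],
               pos = GenomicRanges::start(map)[i], state = states,
               log2Ratio = ifelse(states == "gain", 0.6, -0.6))
}

test_that("a run of same-state calls becomes one segment with marker-position bounds", {
    map <- mkMap()
    calls <- mkCalls(map, c("m01", "m02", "m03"), rep("gain", 3))
    seg <- buildSegments(calls, map, minMarkers = 2, maxGapMarkers = 0)
    expect_length(seg, 1)
    expect_equal(GenomicRanges::start(seg), 100)
    expect_equal(GenomicRanges::end(seg), 300)
    expect_equal(seg$state, "gain")
    expect_equal(seg$nMarkers, 3L)
})

test_that("adjacent gain and loss calls form a mixed segment", {
    map <- mkMap()
    calls <- mkCalls(map, c("m01", "m02"), c("gain", "loss"))
    seg <- buildSegments(calls, map, minMarkers = 2, maxGapMarkers = 0)
    expect_length(seg, 1)
    expect_equal(seg$state, "mixed")
})

test_that("runs are broken by uncalled markers and pruned by minMarkers", {
    map <- mkMap()
    calls <- mkCalls(map, c("m01", "m02", "m04", "m07", "m08", "m09"),
                     rep("gain", 6))
    seg0 <- buildSegments(calls, map, minMarkers = 2, maxGapMarkers = 0)
    expect_equal(GenomicRanges::start(seg0), c(100, 700))
    expect_equal(GenomicRanges::end(seg0), c(200, 900))
    expect_equal(S4Vectors::metadata(seg0)$discardedCalls, 1L)  # lone m04
    # one tolerated gap glues m01..m04 into a single segment
    seg1 <- buildSegments(calls, map, minMarkers = 2, maxGapMarkers = 1)
    expect_equal(GenomicRanges::start(seg1), c(100, 700))
    expect_equal(GenomicRanges::end(seg1), c(400, 900))
    expect_equal(seg1$nMarkers, c(3L, 3L))
})

test_that("calls naming unknown markers are rejected", {
    map <- mkMap()
    calls <- mkCalls(map, c("m01", "m02"), rep("gain", 2))
    calls$marker[2] <- "nope"
    expect_error(buildSegments(calls, map), "absent from the map")
})

test_that("segmentation matches the brute-force run scanner on random calls", {
    set.seed(101)
    for (rep in 1:25) {
        rc <- randomCalls(nCalls = sample(20:120, 1))
        minM <- sample(1:3, 1); gap <- sample(0:2, 1)
        seg <- buildSegments(rc$calls, rc$map, minM, gap)
        ora <- oracleSegments(rc$calls, rc$map, minM, gap)
        if (is.null(ora)) { expect_length(seg, 0); next }
        got <- data.frame(individual = seg$individual,
                          chrom = as.character(GenomicRanges::seqnames(seg)),
                          start = GenomicRanges::start(seg),
                          end = GenomicRanges::end(seg),
                          nMarkers = seg$nMarkers, state = seg$state)
        got <- got[order(got$individual, got$chrom, got$start), ]
        rownames(got) <- rownames(ora) <- NULL
        expect_equal(got, ora[, names(got)])
    }
})

test_that("calls partition into segments plus discards, and segments never overlap", {
    set.seed(77)
    for (rep in 1:10) {
        rc <- randomCalls(nCalls = 150, nInd = 4)
        seg <- buildSegments(rc$calls, rc$map, minMarkers = 3, maxGapMarkers = 0)
        expect_equal(sum(seg$nMarkers) + S4Vectors::metadata(seg)$discardedCalls,
                     nrow(rc$calls))
        for (id in unique(seg$individual)) {
            g <- seg[seg$individual == id]
            hits <- GenomicRanges::findOverlaps(g, g)
            expect_equal(length(hits), length(g))  # self-hits only
        }
    }
})

test_that("segment summary reports per-breed genome percentages with mixed double-counted", {
    sizes <- c(chr1 = 1e6)
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        individual = "i1", state = "gain", nMarkers = 3L, meanLog2Ratio = 0.6)
    labels <- data.frame(individual = c("i1", "i2"), breed = "X", cluster = "X")
    tab <- segmentSummary(gr, labels, sizes)
    per <- attr(tab, "perIndividual")
    expect_equal(per$gainPct[per$individual == "i1"], 1.0)
    expect_equal(per$lossPct[per$individual == "i1"], 0.0)
    expect_equal(tab$meanTotalPct, 0.5)  # i2 contributes zero

    gr$state <- "mixed"
    tab2 <- segmentSummary(gr, labels, sizes)
    per2 <- attr(tab2, "perIndividual")
    expect_equal(per2$gainPct[1], 1.0)
    expect_equal(per2$lossPct[1], 1.0)
})

test_that("per-individual percentages match an interval-union oracle", {
    set.seed(55)
    sizes <- c(chr1 = 2e5, chr2 = 2e5)
    rs <- randomSegments(60)
    labels <- data.frame(individual = sprintf("i%02d", 1:8),
                         breed = rep(c("X", "Y"), each = 4),
                         cluster = rep(c("X", "Y"), each = 4))
    tab <- segmentSummary(rs$gr, labels, sizes)
    per <- attr(tab, "perIndividual")
    for (id in labels$individual) {
        d <- rs$df[rs$df$individual == id, ]
        want <- if (!nrow(d)) 0 else 100 * sum(vapply(unique(d$chrom),
            function(ch) oracleUnionLength(d$start[d$chrom == ch],
                                           d$end[d$chrom == ch]),
            numeric(1))) / sum(sizes)
        expect_equal(per$totalPct[per$individual == id], want,
                     tolerance = 1e-9)
    }
    # breed rows are plain mean/sd of the per-individual values
    x <- per$totalPct[per$breed == "X"]
    expect_equal(tab$meanTotalPct[tab$breed == "X"], mean(x))
    expect_equal(tab$sdTotalPct[tab$breed == "X"], sd(x))
})

test_that("segments beyond the chromosome end are rejected", {
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2e6))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        individual = "i1", state = "gain", nMarkers = 3L, meanLog2Ratio = 0.6)
    labels <- data.frame(individual = "i1", breed = "X", cluster = "X")
    expect_error(segmentSummary(gr, labels, c(chr1 = 1e6)), "beyond")
})
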