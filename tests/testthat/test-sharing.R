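mkLabels <- function(sizes, clusters = NULL) {
    if (is.null(clusters)) clusters <- names(sizes)
    data.frame(individual = unlist(lapply(names(sizes), function(g)
                   sprintf("%s_%02d", g, seq_len(sizes[[g]])))),
               breed = rep(names(sizes), unlist(sizes)),
               cluster = rep(clusters, unlist(sizes)))
}

mkCall <- function(individual, pos, state, chrom = "chr1") {
    data.frame(individual = individual, marker = sprintf("m%d", pos),
               chrom = chrom, pos = pos, state = state,
               log2Ratio = ifelse(state == "gain", 0.5, -0.5))
}

test_that("the 1% filter is boundary-inclusive and uses group size, not carriers", {
    labels <- mkLabels(list(A = 100, B = 24))
    calls <- rbind(mkCall("A_01", 500, "gain"), mkCall("B_01", 700, "gain"))
    ft <- positionFrequency(calls, labels, "breed", minFraction = 0.01)
    a <- ft[ft$group == "A", ]
    expect_equal(a$fraction, 0.01)
    expect_true(a$retained)           # exactly 1% of 100 stays in
    b <- ft[ft$group == "B", ]
    expect_equal(b$fraction, 1 / 24, tolerance = 1e-12)
    expect_true(b$retained)
})

test_that("unlabelled individuals are rejected", {
    labels <- mkLabels(list(A = 3))
    expect_error(positionFrequency(mkCall("ghost", 1, "gain"), labels, "breed"),
                 "unlabelled")
})

test_that("a single carrier elsewhere defeats privacy; states stay independent", {
    labels <- mkLabels(list(A = 20, B = 20))
    # gain at 500 retained in A (10%), one carrier in B -> not private to A
    calls <- rbind(mkCall(c("A_01", "A_02"), 500, "gain"),
                   mkCall("B_01", 500, "gain"),
                   # gain at 900 in A only, loss at 900 in B only
                   mkCall("A_03", 900, "gain"),
                   mkCall("B_02", 900, "loss"))
    ft <- positionFrequency(calls, labels, "breed", 0.01)
    up <- uniquePrivate(ft)
    pos <- up$positions
    expect_false(pos$private[pos$group == "A" & pos$pos == 500])
    expect_true(pos$private[pos$group == "A" & pos$pos == 900 &
                            pos$state == "gain"])
    expect_true(pos$private[pos$group == "B" & pos$pos == 900 &
                            pos$state == "loss"])
})

test_that("privacy below the retention threshold is not reported", {
    labels <- mkLabels(list(A = 200, B = 20))
    calls <- mkCall("A_01", 500, "gain")  # 0.5% of A, nowhere else
    ft <- positionFrequency(calls, labels, "breed", 0.01)
    up <- uniquePrivate(ft)
    expect_equal(nrow(up$positions), 0)
    expect_equal(up$report$nPositions[up$report$group == "A" &
                                      up$report$state == "gain"], 0)
})

test_that("frequency tables and privacy match brute-force set oracles", {
    set.seed(606)
    for (rep in 1:15) {
        labels <- mkLabels(list(A = 10, B = 15, C = 8))
        n <- sample(30:90, 1)
        calls <- data.frame(
            individual = sample(labels$individual, n, replace = TRUE),
            marker = "m", chrom = sample(c("chr1", "chr2"), n, TRUE),
            pos = sample(1:12, n, TRUE) * 100,
            state = sample(c("gain", "loss"), n, TRUE), log2Ratio = 0.5)
        calls <- calls[!duplicated(calls[, c("individual", "chrom", "pos", "state")]), ]
        ft <- positionFrequency(calls, labels, "breed", 0.1)
        ora <- oraclePositionFrequency(calls, labels, "breed", 0.1)
        rownames(ft) <- rownames(ora) <- NULL
        attributes(ft)[c("groupSizes", "groupBy", "minFraction")] <- NULL
        expect_equal(ft, ora)

        ftF <- positionFrequency(calls, labels, "breed", 0.1)
        up <- uniquePrivate(ftF)
        oraPriv <- oracleUniquePrivate(ftF)[ftF$retained]
        expect_equal(up$positions$private, unname(oraPriv))
    }
})

test_that("collapsing breeds into clusters never creates privacy", {
    set.seed(707)
    labels <- mkLabels(list(A = 10, B = 10, C = 10),
                       clusters = c("c1", "c1", "c2"))
    n <- 80
    calls <- data.frame(
        individual = sample(labels$individual, n, replace = TRUE),
        marker = "m", chrom = "chr1", pos = sample(1:15, n, TRUE) * 100,
        state = sample(c("gain", "loss"), n, TRUE), log2Ratio = 0.5)
    calls <- calls[!duplicated(calls[, c("individual", "chrom", "pos", "state")]), ]
    upB <- uniquePrivate(positionFrequency(calls, labels, "breed", 0.01))
    upC <- uniquePrivate(positionFrequency(calls, labels, "cluster", 0.01))
    # a (pos, state) private at cluster level must not be shared across
    # clusters at breed level: sharing can only be discovered within a cluster
    keyC <- with(upC$positions[upC$positions$private, ],
                 paste(chrom, pos, state))
    breedShared <- with(upB$positions[!upB$positions$private, ],
                        paste(chrom, pos, state))
    crossBreed <- vapply(breedShared, function(k) {
        rows <- upB$positions[paste(upB$positions$chrom, upB$positions$pos,
                                    upB$positions$state) == k, ]
        length(unique(labels$cluster[match(rows$group, labels$breed)])) > 1
    }, logical(1))
    expect_false(any(keyC %in% breedShared[crossBreed]))
    # a position can be private to at most one group
    k <- with(upB$positions[upB$positions$private, ], paste(chrom, pos, state))
    expect_false(any(duplicated(k)))
})

test_that("report percentages recompute from their own columns", {
    s <- smallSim()
    prof <- buildReferenceProfile(s$sim$cohort, "Ref")
    calls <- callSnpCnvs(s$sim$cohort, prof)
    up <- uniquePrivate(positionFrequency(calls, sampleInfo(s$sim$cohort),
                                          "breed", 0.01))
    rep <- up$report
    nz <- rep$nPositions > 0
    expect_equal(rep$pctUniquePrivate[nz],
                 100 * rep$nUniquePrivate[nz] / rep$nPositions[nz])
    expect_true(all(rep$nUniquePrivate <= rep$nPositions))
    expect_true(all(rep$pctUniquePrivate >= 0 & rep$pctUniquePrivate <= 100))
})

test_that("bracketed averages are positions over group size", {
    labels <- mkLabels(list(A = 40))
    calls <- do.call(rbind, lapply(1:13, function(p) mkCall("A_01", p * 100, "gain")))
    calls <- rbind(calls, mkCall("A_02", 1300, "loss"))
    ft <- positionFrequency(calls, labels, "breed", 0.01)
    bs <- breedSummary(ft)
    expect_equal(bs$nPositions[bs$state == "gain"], 13)
    expect_equal(bs$avgPerIndividual[bs$state == "gain"], 13 / 40)
    # empty state: average 0
    expect_equal(bs$avgPerIndividual[bs$state == "loss"], 1 / 40)
    d <- averageCallsPerIndividual(calls, labels, "breed")
    expect_equal(d$meanCallsPerIndividual[d$state == "gain"], 13 / 40)
})

test_that("private chromosome profiles highlight strictly above threshold", {
    labels <- mkLabels(list(A = 256, B = 10))
    calls <- do.call(rbind, lapply(sprintf("A_%02d", 1:52),
                                   function(i) mkCall(i, 500, "gain")))
    ft <- positionFrequency(calls, labels, "breed", 0.01)
    up <- uniquePrivate(ft)
    prof <- privateChromosomeProfile(up, highlightThreshold = 20)
    expect_equal(prof$track$carrierPct, 100 * 52 / 256, tolerance = 1e-9)
    expect_equal(nrow(prof$highlight), 1)   # 20.3% > 20%
    prof2 <- privateChromosomeProfile(up, highlightThreshold = 20.3125)
    expect_equal(nrow(prof2$highlight), 0)  # boundary is strict
})
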