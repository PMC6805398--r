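test_that("noise-free, CNV-free cohort sits exactly at the diploid baseline", {
    cfg <- simConfig(seed = 5, nAutosomes = 1, nMarkersPerChrom = 40,
                     breeds = data.frame(name = c("R", "X"), n = c(3, 3),
                                         cluster = c("c1", "c2")),
                     referenceBreed = "R", plantedCnvrs = NULL,
                     noiseSd = 0, bafNoiseSd = 0)
    sim <- simulateCohort(cfg)
    lr <- log2(intensity(sim$cohort) / S4Vectors::metadata(sim$cohort)$baseline)
    expect_true(all(lr == 0))
    expect_null(sim$truth$regions)
})

test_that("a fixed seed yields bit-identical cohorts and truth tables", {
    s <- smallSim()
    sim2 <- simulateCohort(s$cfg)
    expect_identical(intensity(s$sim$cohort), intensity(sim2$cohort))
    expect_identical(baf(s$sim$cohort), baf(sim2$cohort))
    expect_identical(s$sim$truth, sim2$truth)
})

test_that("noise-free planted carriers show log2 ratios of exactly log2(copy/2)", {
    cfg <- simConfig(seed = 8, nAutosomes = 1, chromLengthBp = 1e6,
                     nMarkersPerChrom = 20,
                     breeds = data.frame(name = c("R", "X"), n = c(4, 10),
                                         cluster = c("c1", "c2")),
                     referenceBreed = "R",
                     plantedCnvrs = plantedCnvr("chr1", 300001, 700000, 3L,
                                                "X", 0.5),
                     noiseSd = 0, bafNoiseSd = 0)
    sim <- simulateCohort(cfg)
    base <- S4Vectors::metadata(sim$cohort)$baseline
    lr <- log2(intensity(sim$cohort) / base)
    map <- markerMap(sim$cohort)
    inside <- GenomicRanges::start(map) >= 300001 &
        GenomicRanges::start(map) <= 700000
    carr <- sim$truth$carriers
    for (id in carr$individual)
        expect_equal(unname(lr[inside, id]),
                     rep(if (carr$carrier[carr$individual == id])
                             log2(3 / 2) else 0, sum(inside)))
    expect_true(all(lr[!inside, ] == 0))
})

test_that("overlapping planted regions with conflicting copy numbers are rejected", {
    pl <- rbind(plantedCnvr("chr1", 100, 5000, 3L, "X", 0.5),
                plantedCnvr("chr1", 4000, 9000, 1L, "X", 0.5))
    expect_error(
        simConfig(nAutosomes = 1, nMarkersPerChrom = 10, chromLengthBp = 1e4,
                  breeds = data.frame(name = "X", n = 5, cluster = "c"),
                  referenceBreed = "X", plantedCnvrs = pl),
        "conflicting copy numbers")
})

test_that("an expected carrier count below one triggers a warning, not an error", {
    cfg <- simConfig(seed = 2, nAutosomes = 1, nMarkersPerChrom = 10,
                     chromLengthBp = 1e4,
                     breeds = data.frame(name = "X", n = 5, cluster = "c"),
                     referenceBreed = "X",
                     plantedCnvrs = plantedCnvr("chr1", 1000, 9000, 3L, "X", 0.1))
    expect_warning(simulateCohort(cfg), "below 1")
})

test_that("truth BED uses 0-based half-open coordinates and round-trips", {
    s <- smallSim()
    path <- withr::local_tempfile(fileext = ".bed")
    writeTruthBed(s$sim$truth, path)
    reg <- s$sim$truth$regions
    gr <- readBed(path)
    expect_length(gr, nrow(reg))  # one record per region x carrier group
    raw <- read.table(path, sep = "\t")
    expect_equal(raw$V2, reg$start - 1L)
    expect_equal(raw$V3, reg$end)
    expect_equal(GenomicRanges::start(gr), reg$start)
    expect_equal(GenomicRanges::end(gr), reg$end)
})

test_that("an empty truth table writes an empty file without error", {
    cfg <- simConfig(seed = 5, nAutosomes = 1, nMarkersPerChrom = 10,
                     chromLengthBp = 1e4,
                     breeds = data.frame(name = "X", n = 3, cluster = "c"),
                     referenceBreed = "X", plantedCnvrs = NULL)
    sim <- simulateCohort(cfg)
    path <- withr::local_tempfile(fileext = ".bed")
    expect_no_error(writeTruthBed(sim$truth, path))
    expect_length(readBed(path), 0)
})

test_that("carrier counts are binomial around the planted frequency", {
    # 30 disjoint regions x n=400 at f = 0.3: total carriers ~ Binom(12000, 0.3)
    pl <- do.call(rbind, lapply(seq_len(30), function(k)
        plantedCnvr("chr1", (k - 1) * 3e4 + 1, (k - 1) * 3e4 + 25000, 3L,
                    "X", 0.3, id = sprintf("r%02d", k))))
    cfg <- simConfig(seed = 31, nAutosomes = 1, chromLengthBp = 1e6,
                     nMarkersPerChrom = 100,
                     breeds = data.frame(name = "X", n = 400, cluster = "c"),
                     referenceBreed = "X", plantedCnvrs = pl,
                     noiseSd = 0, bafNoiseSd = 0)
    sim <- simulateCohort(cfg)
    tot <- sum(sim$truth$regions$nCarriers)
    ntr <- 30 * 400
    z <- (tot - ntr * 0.3) / sqrt(ntr * 0.3 * 0.7)
    expect_lt(abs(z), 4)
    # per-region chi-square against Binom(400, 0.3)
    chi <- sum((sim$truth$regions$nCarriers - 120)^2 / (400 * 0.3 * 0.7))
    expect_lt(chi, qchisq(1 - 1e-6, df = 30))
})

test_that("BAF clusters follow the local copy number", {
    cfg <- simConfig(seed = 12, nAutosomes = 1, chromLengthBp = 1e6,
                     nMarkersPerChrom = 100,
                     breeds = data.frame(name = c("R", "X"), n = c(4, 30),
                                         cluster = c("c1", "c2")),
                     referenceBreed = "R",
                     plantedCnvrs = plantedCnvr("chr1", 1, 1e6, 1L, "X", 1),
                     noiseSd = 0, bafNoiseSd = 0)
    sim <- simulateCohort(cfg)
    b <- baf(sim$cohort)
    xcols <- grepl("^X_", colnames(b))
    expect_true(all(b[, xcols] %in% c(0, 1)))          # hemizygous
    expect_true(all(b[, !xcols] %in% c(0, 0.5, 1)))    # diploid
})

test_that("YAML simulation configs round-trip through readSimConfig", {
    path <- withr::local_tempfile(fileext = ".yaml")
    yaml::write_yaml(list(
        seed = 4, nAutosomes = 1, chromLengthBp = 1e5, nMarkersPerChrom = 20,
        breeds = list(list(name = "R", n = 3, cluster = "c1"),
                      list(name = "X", n = 5, cluster = "c2")),
        referenceBreed = "R",
        plantedCnvrs = list(list(chrom = "chr1", start = 10001, end = 60000,
                                 copyNumber = 3, carrierGroups = "X",
                                 carrierFrequency = 0.5, id = "p1"))), path)
    cfg <- readSimConfig(path)
    expect_s3_class(cfg, "SimConfig")
    expect_identical(cfg$breeds$name, c("R", "X"))
    expect_identical(cfg$plantedCnvrs$id, "p1")
    expect_no_error(simulateCohort(cfg))
})
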