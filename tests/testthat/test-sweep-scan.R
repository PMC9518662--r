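test_that("the Z-transform standardizes to mean 0, sample sd 1", {
    expect_equal(zTransform(c(0, 1)), c(-1, 1) / sqrt(2), tolerance = 1e-6)
    set.seed(2)
    z <- zTransform(runif(50))
    expect_equal(mean(z), 0)
    expect_equal(sd(z), 1)
    expect_error(zTransform(rep(0.3, 10)), "degenerate")
    expect_error(zTransform(0.5), "at least two")
})

test_that("the focal log2 ratio is antisymmetric and pseudocount-bounded", {
    expect_equal(log2PiRatio(1e-3, 1e-3), 0)
    expect_equal(log2PiRatio(0, 1e-3), log2(1e-8 / (1e-3 + 1e-8)),
                 tolerance = 1e-9)
    expect_equal(log2PiRatio(0, 1e-3), -16.61, tolerance = 1e-3)
    # swapping focal negates the ratio when both diversities dominate eps
    a <- 2e-4; b <- 7e-4
    expect_equal(log2PiRatio(a, b), -log2PiRatio(b, a), tolerance = 1e-6)
})

test_that("joint tails select exactly the constructed outlier windows", {
    # 100 windows, monotone scores: extremes coincide in the last windows
    n <- 100
    win <- data.frame(chrom = "chr1",
                      start = seq(1, by = 10000, length.out = n))
    win$end <- win$start + 19999
    win$n_snps <- 15L
    win$fst <- seq(0.01, 0.99, length.out = n)
    win$pi_fast <- seq(2e-3, 1e-5, length.out = n)
    win$pi_slow <- 1e-3
    sc <- selectCandidates(win, focal = "fast")
    # brute force over the same vectors
    z <- (win$fst - mean(win$fst)) / sd(win$fst)
    ratio <- log2((win$pi_fast + 1e-8) / (win$pi_slow + 1e-8))
    expected <- which(z >= quantile(z, 0.95) & ratio <= quantile(ratio, 0.05))
    expect_identical(which(win$start %in% selectedWindows(sc)$start),
                     expected)
    expect_length(expected, 5L)
    # selection count is bounded by either single tail
    expect_lte(nrow(selectedWindows(sc)),
               min(sum(z >= quantile(z, 0.95)),
                   sum(ratio <= quantile(ratio, 0.05))))
})

test_that("extreme quantiles reduce the selection to argmax/argmin", {
    n <- 30
    set.seed(8)
    win <- data.frame(chrom = "chr1",
                      start = seq(1, by = 10000, length.out = n))
    win$end <- win$start + 19999
    win$n_snps <- 12L
    win$fst <- runif(n)
    win$pi_fast <- runif(n, 1e-5, 1e-3)
    win$pi_slow <- runif(n, 1e-5, 1e-3)
    # make one window the joint extreme
    win$fst[17] <- 2
    win$pi_fast[17] <- 0
    sc <- selectCandidates(win, "fast", fstQuantile = 1, ratioQuantile = 0)
    expect_identical(selectedWindows(sc)$start, win$start[17])
})

test_that("too few windows or no joint outlier are handled explicitly", {
    win <- data.frame(chrom = "chr1", start = seq(1, by = 10000, length.out = 10))
    win$end <- win$start + 19999
    win$n_snps <- 12L; win$fst <- runif(10)
    win$pi_fast <- 1e-4; win$pi_slow <- 1e-4
    expect_error(selectCandidates(win, "fast"), "fewer than 20")
})

test_that("overlapping and book-ended selected windows merge; distinct ones do not", {
    win <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                      start = c(1, 10001, 50001, 10001),
                      end = c(20000, 30000, 70000, 30000),
                      z = c(3, 4, 5, 6), log2_ratio = c(-2, -3, -1, -4))
    reg <- mergeRegions(win, focal = "fast")
    expect_length(reg, 3L)
    expect_identical(start(reg), c(1L, 50001L, 10001L))
    expect_identical(end(reg), c(30000L, 70000L, 30000L))
    expect_identical(reg$n_windows, c(2L, 1L, 1L))
    expect_equal(reg$max_z[1], 4)
    expect_equal(reg$min_ratio[1], -3)
    # abutting windows (book-ended on the lattice) merge too
    ab <- data.frame(chrom = "chr1", start = c(1, 20001), end = c(20000, 40000))
    expect_length(mergeRegions(ab), 1L)
    # k disjoint windows give k regions
    dj <- data.frame(chrom = "chr1", start = c(1, 40001, 80001),
                     end = c(20000, 60000, 100000))
    expect_length(mergeRegions(dj), 3L)
})

test_that("swapping population labels mirrors the scan", {
    sw <- GRanges("chr1", IRanges(4e5, 5e5), focal = "fast", strength = 1)
    sim <- simulatePanel(SimConfig(sweepRegions = sw, seed = 14L,
                                   missingRate = 0, lowGqRate = 0))
    win <- windowStats(sim$panel)
    # mirror the panel: relabel fast<->slow by swapping the pi columns
    winM <- win
    winM$pi_fast <- win$pi_slow
    winM$pi_slow <- win$pi_fast
    sc <- selectCandidates(win, "fast")
    scM <- selectCandidates(winM, "slow")
    expect_identical(selectedWindows(sc)$start, selectedWindows(scM)$start)
    expect_equal(sc@zThreshold, scM@zThreshold)
    expect_equal(sc@ratioThreshold, scM@ratioThreshold)
})

test_that("a planted full-strength sweep yields an overlapping candidate region", {
    sw <- GRanges("chr1", IRanges(5e5, 6e5), focal = "fast", strength = 1)
    sim <- simulatePanel(SimConfig(sweepRegions = sw, seed = 3L))
    flt <- applySiteFilters(sim$panel)
    sc <- selectCandidates(windowStats(flt), "fast")
    reg <- candidateRegions(sc)
    expect_gte(length(reg), 1L)
    expect_true(any(countOverlaps(sw, reg) > 0))
    # every selected window satisfies both thresholds
    selw <- selectedWindows(sc)
    expect_true(all(selw$z >= sc@zThreshold))
    expect_true(all(selw$log2_ratio <= sc@ratioThreshold))
})

test_that("candidate regions export to BED as 0-based half-open intervals", {
    win <- data.frame(chrom = "chr1", start = c(10001, 20001),
                      end = c(30000, 40000), z = c(3, 4),
                      log2_ratio = c(-5, -6))
    sc <- new("ScanResult", focal = "fast", zThreshold = 2,
              ratioThreshold = -1, windows = win,
              regions = mergeRegions(win, "fast"))
    bed <- withr::local_tempfile(fileext = ".bed")
    writeRegionsBed(sc, bed)
    fields <- strsplit(readLines(bed), "\t")[[1]]
    expect_identical(fields[1:3], c("chr1", "10000", "40000"))
})
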