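test_that("exact-boundary sites fail the strict filters", {
    # 14 samples (4 fast + 10 slow), sites built to sit on the call-rate
    # and GQ boundaries
    pop <- c(rep("fast", 4), rep("slow", 10))
    # site 1: all called, pooled p = 0.5                      -> kept
    # site 2: 13/14 called (0.929 > 0.9)                      -> kept
    # site 3: one NA + one GQ=10 masked -> 12/14 = 0.857      -> dropped
    # site 4: one NA + one GQ=11 (not masked) -> 13/14        -> kept
    gt <- rbind(
        rep(1L, 14),
        c(NA, rep(1L, 13)),
        c(NA, rep(1L, 13)),
        c(NA, rep(1L, 13)))
    gq <- matrix(99L, 4, 14)
    gq[3, 2] <- 10L   # GQ = 10 is not > 10: masked
    gq[4, 2] <- 11L   # survives
    gq[is.na(gt)] <- NA_integer_
    panel <- makePanel(gt, pop, gq = gq)
    flt <- applySiteFilters(panel)
    expect_identical(start(rowRanges(flt)), c(1L, 2L, 4L))
    rep <- filterReport(flt)
    expect_identical(rep$genotypesMaskedGQ, 1L)
    expect_identical(rep$removedCallRate, 1L)
    expect_identical(rep$removedMAF, 0L)

    # MAF boundary needs 20 pooled alleles: 10 samples, all called;
    # one alt allele gives p = 0.05 exactly, which is not > 0.05
    pop10 <- c(rep("fast", 4), rep("slow", 6))
    gt10 <- rbind(c(1L, rep(0L, 9)),      # MAF 0.05 -> dropped
                  c(1L, 1L, rep(0L, 8)))  # MAF 0.10 -> kept
    flt10 <- applySiteFilters(makePanel(gt10, pop10))
    expect_identical(start(rowRanges(flt10)), 2L)
    expect_identical(filterReport(flt10)$removedMAF, 1L)
})

test_that("call rate 13/14 passes the 0.9 threshold", {
    expect_gt(13 / 14, 0.9)
    pop <- c(rep("fast", 4), rep("slow", 10))
    gt <- matrix(1L, 1, 14)
    gt[1, 5] <- NA
    flt <- applySiteFilters(makePanel(gt, pop))
    expect_identical(nrow(flt), 1L)
})

test_that("filtering is idempotent and monotone in the thresholds", {
    set.seed(7)
    for (i in 1:100) {
        panel <- randomPanel(nSites = 30L, nFast = 3L, nSlow = 4L,
                             missingRate = 0.15)
        thr <- list(gq = sample(c(5, 10, 20), 1),
                    maf = runif(1, 0, 0.3),
                    cr = runif(1, 0.3, 0.95))
        f1 <- tryCatch(applySiteFilters(panel, thr$gq, thr$maf, thr$cr),
                       error = function(e) NULL)
        if (is.null(f1)) next
        f2 <- applySiteFilters(f1, thr$gq, thr$maf, thr$cr)
        expect_identical(genotypes(f2), genotypes(f1))
        expect_identical(start(rowRanges(f2)), start(rowRanges(f1)))
        # raising any threshold never increases the retained count
        harder <- tryCatch(
            applySiteFilters(panel, thr$gq + 5, thr$maf + 0.05,
                             min(thr$cr + 0.05, 1)),
            error = function(e) NULL)
        nHarder <- if (is.null(harder)) 0L else nrow(harder)
        expect_lte(nHarder, nrow(f1))
    }
})

test_that("site decisions agree with a per-site brute-force checker", {
    set.seed(21)
    for (i in 1:25) {
        panel <- randomPanel(nSites = 12L, nFast = 3L, nSlow = 3L,
                             missingRate = 0.2)
        gq <- genoQual(panel)
        gq[sample(length(gq), 8)] <- sample(c(5L, 10L, 11L), 8, TRUE)
        gq[is.na(genotypes(panel))] <- NA_integer_
        panel <- makePanel(genotypes(panel), populations(panel),
                           pos = start(rowRanges(panel)), gq = gq)
        expected <- vapply(seq_len(nrow(panel)), function(s) {
            g <- genotypes(panel)[s, ]
            q <- gq[s, ]
            g[!is.na(q) & q <= 10] <- NA
            called <- sum(!is.na(g))
            if (called / length(g) <= 0.9) return(FALSE)
            p <- sum(g, na.rm = TRUE) / (2 * called)
            min(p, 1 - p) > 0.05
        }, logical(1))
        got <- tryCatch(
            start(rowRanges(applySiteFilters(panel))),
            error = function(e) integer(0))
        expect_identical(got, start(rowRanges(panel))[expected])
    }
})

test_that("an over-aggressive filter fails loudly instead of silently", {
    # both sites monomorphic: MAF 0 can never pass
    panel <- makePanel(matrix(0L, 2, 6), c(rep("fast", 3), rep("slow", 3)))
    expect_error(applySiteFilters(panel), "review")
})

test_that("indels and multiallelic records are skipped on load", {
    vcf <- withr::local_tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"GQ\">",
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
        "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:GQ\t0/1:99\t./.:.",
        "chr1\t200\t.\tA\tAT\t.\tPASS\t.\tGT:GQ\t0/1:99\t0/0:99",
        "chr1\t300\t.\tC\tG,T\t.\tPASS\t.\tGT:GQ\t1/2:99\t0/0:99"),
        vcf)
    pm <- c(s1 = "fast", s2 = "slow")
    panel <- suppressMessages(loadPanel(vcf, pm))
    expect_identical(nrow(panel), 1L)
    expect_identical(start(rowRanges(panel)), 100L)
    # missing genotype loads as NA dosage
    expect_identical(unname(genotypes(panel)[1, "s2"]), NA_integer_)
    expect_error(loadPanel(vcf, c(s1 = "fast")), "absent from popmap")
})
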