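test_that("same seed and config reproduce the identical panel", {
    cfg <- SimConfig(chromLengths = c(chr1 = 2e5), seed = 9L)
    s1 <- simulatePanel(cfg)
    s2 <- simulatePanel(cfg)
    expect_identical(genotypes(s1$panel), genotypes(s2$panel))
    expect_identical(genoQual(s1$panel), genoQual(s2$panel))
    expect_identical(s1$truth$siteFreq, s2$truth$siteFreq)
})

test_that("no divergence and no sweeps gives near-zero FST", {
    cfg <- SimConfig(nFast = 20L, nSlow = 20L,
                     chromLengths = c(chr1 = 5e5), snpDensity = 2e-2,
                     divergenceF = 1e-4, missingRate = 0, lowGqRate = 0,
                     seed = 2L)
    sim <- simulatePanel(cfg)
    win <- windowStats(sim$panel, minSnps = 1L)
    # ratio-of-sums FST over ~10k near-undifferentiated sites
    expect_lt(abs(mean(win$fst)), 0.01)
})

test_that("a full-strength sweep depresses focal diversity inside the region", {
    sw <- GRanges("chr1", IRanges(5e5, 6e5), focal = "fast", strength = 1)
    sim <- simulatePanel(SimConfig(sweepRegions = sw, seed = 4L))
    win <- windowStats(sim$panel, minSnps = 1L)
    inside <- win$start >= 5e5 & win$end <= 6e5
    expect_true(any(inside))
    expect_lt(mean(win$pi_fast[inside]), mean(win$pi_fast[!inside]))
    # the slow population is untouched by the fast-focal sweep
    expect_gt(mean(win$pi_slow[inside]), mean(win$pi_fast[inside]))
})

test_that("simulated population frequencies follow the divergence parameter", {
    # mean per-site Weir-Cockerham theta over many neutral sites should sit
    # near the Balding-Nichols F that generated them
    cfg <- SimConfig(nFast = 30L, nSlow = 30L,
                     chromLengths = c(chr1 = 1e6), snpDensity = 2e-2,
                     divergenceF = 0.1, missingRate = 0, lowGqRate = 0,
                     seed = 6L)
    sim <- simulatePanel(cfg)
    win <- windowStats(sim$panel, window = 1e6, step = 1e6, minSnps = 1L)
    expect_gt(nrow(sim$panel), 1e4)
    # ratio-of-sums theta across ~20k sites; Monte-Carlo slack
    expect_lt(abs(win$fst - 0.1), 0.02)
})

test_that("overlapping sweep regions are rejected as ambiguous truth", {
    sw <- GRanges("chr1", IRanges(c(1e5, 1.5e5), c(2e5, 2.5e5)),
                  focal = c("fast", "slow"), strength = c(1, 1))
    expect_error(SimConfig(sweepRegions = sw), "overlapping")
})

test_that("sweep regions outside their chromosome are rejected", {
    sw <- GRanges("chr1", IRanges(1.9e6, 2.1e6), focal = "fast",
                  strength = 1)
    expect_error(SimConfig(chromLengths = c(chr1 = 2e6),
                           sweepRegions = sw), "within their chromosome")
})

test_that("simulated reads carry the requested QC violations", {
    fq <- withr::local_tempfile(fileext = ".fastq")
    n <- simulateReads(fq, clean = 10L, adapter = 2L, highN = 1L,
                       lowQ = 1L, seed = 5L)
    expect_identical(n, 14L)
    expect_identical(length(readLines(fq)), 56L)
    kept <- filterReads(fq, adapters = "AGATCGGAAGAGC")
    expect_identical(length(kept$seqs), 10L)
    expect_identical(unname(kept$reasons),
                     c(10L, 2L, 1L, 1L))
    expect_error(simulateReads(fq, clean = -1L), "non-negative")
})

test_that("simulated annotation stays within bounds and is deterministic", {
    lens <- c(chr1 = 5e5, chr2 = 3e5)
    a1 <- simulateAnnotation(lens, nGenes = 40L, nTerms = 10L, seed = 3L)
    a2 <- simulateAnnotation(lens, nGenes = 40L, nTerms = 10L, seed = 3L)
    expect_identical(a1$termMap, a2$termMap)
    expect_identical(as.data.frame(a1$genes), as.data.frame(a2$genes))
    expect_length(a1$genes, 40L)
    expect_true(all(start(a1$genes) >= 1))
    expect_true(all(end(a1$genes) <=
        lens[as.character(seqnames(a1$genes))]))
    # non-overlapping intervals per chromosome
    expect_length(reduce(a1$genes, min.gapwidth = 0L), 40L)
    perGene <- table(a1$termMap$gene)
    expect_true(all(perGene >= 1 & perGene <= 5))
    empty <- simulateAnnotation(lens, nGenes = 0L, nTerms = 5L, seed = 1L)
    expect_length(empty$genes, 0L)
})

test_that("VCF round trip preserves genotypes and qualities", {
    sim <- simulatePanel(SimConfig(chromLengths = c(chr1 = 1e5),
                                   snpDensity = 2e-3, seed = 8L))
    vcf <- withr::local_tempfile(fileext = ".vcf")
    writePanelVcf(sim$panel, vcf)
    lines <- readLines(vcf)
    expect_match(lines[1], "^##fileformat=VCFv4")
    body <- lines[!startsWith(lines, "#")]
    expect_length(body, nrow(sim$panel))
    back <- loadPanel(vcf, setNames(populations(sim$panel),
                                    colnames(sim$panel)))
    expect_identical(genotypes(back), genotypes(sim$panel))
    expect_identical(unname(genoQual(back)), unname(genoQual(sim$panel)))
    # missing genotypes serialize as ./.
    if (anyNA(genotypes(sim$panel)))
        expect_true(any(grepl("\\./\\.", body)))
})
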