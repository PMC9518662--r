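suppressPackageStartupMessages({
    library(GenomicRanges)
    library(SummarizedExperiment)
})

# Literal scalar transcription of the two-population Weir-Cockerham (1984)
# variance components, kept deliberately independent of the vectorized
# implementation under test.
oracleWc <- function(n1, n2, p1, p2, h1, h2) {
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
        (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
        hbar * (2 * nbar - 1) / (4 * nbar))
    c(a = a, b = b, c = hbar / 2)
}

# Direct pair enumeration: per site, fraction of differing pairs among all
# unordered pairs of called alleles; windowed diversity sums these and
# divides by the window length.
oraclePi <- function(gt) {
    vapply(seq_len(nrow(gt)), function(i) {
        g <- gt[i, ]
        alleles <- unlist(lapply(g[!is.na(g)], function(d)
            c(rep(1L, d), rep(0L, 2L - d))))
        n <- length(alleles)
        if (n < 2L) return(0)
        diffs <- 0L
        for (x in seq_len(n - 1L))
            for (y in seq.int(x + 1L, n))
                diffs <- diffs + (alleles[x] != alleles[y])
        diffs / choose(n, 2)
    }, numeric(1))
}

# Quick panel constructor for hand-built fixtures.
makePanel <- function(gt, pop, pos = seq_len(nrow(gt)), chrom = "chr1",
                      gq = NULL, chromLen = NA) {
    gt <- as.matrix(gt)
    storage.mode(gt) <- "integer"
    if (is.null(gq)) {
        gq <- matrix(99L, nrow(gt), ncol(gt))
        gq[is.na(gt)] <- NA_integer_
    }
    sl <- if (is.na(chromLen)) NULL else setNames(chromLen, chrom)
    sites <- GRanges(chrom, IRanges(pos, width = 1L),
                     ref = rep("A", nrow(gt)), alt = rep("G", nrow(gt)),
                     seqlengths = sl)
    PopulationPanel(gt, gq, sites, population = pop)
}

randomPanel <- function(nSites = 20L, nFast = 4L, nSlow = 4L,
                        missingRate = 0.1, chromLen = 20000L) {
    n <- nFast + nSlow
    gt <- matrix(sample(0:2, nSites * n, TRUE), nSites, n)
    gt[runif(length(gt)) < missingRate] <- NA_integer_
    makePanel(gt, c(rep("fast", nFast), rep("slow", nSlow)),
              pos = sort(sample.int(chromLen, nSites)),
              chromLen = chromLen)
}
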