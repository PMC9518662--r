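#' Per-site Weir-Cockerham variance components
#'
#' Computes the two-population (r = 2) Weir & Cockerham (1984) variance
#' components for one or more biallelic sites. The per-site estimator of
#' differentiation is \eqn{\theta = a / (a + b + c)}; a windowed estimate
#' sums each component over the window's sites before taking the ratio
#' ("ratio of sums", the weighted windowed FST of VCFtools).
#'
#' With \eqn{r = 2}, \eqn{\bar n = (n_1+n_2)/2},
#' \eqn{n_c = (r\bar n - (n_1^2+n_2^2)/(r\bar n))/(r-1)},
#' \eqn{\bar p = (n_1 p_1 + n_2 p_2)/(r\bar n)},
#' \eqn{s^2 = (n_1(p_1-\bar p)^2 + n_2(p_2-\bar p)^2)/((r-1)\bar n)} and
#' \eqn{\bar h = (n_1 h_1 + n_2 h_2)/(r\bar n)}:
#' \deqn{a = \frac{\bar n}{n_c}\Big(s^2 - \frac{1}{\bar n - 1}\big(\bar p(1-\bar p) - \frac{r-1}{r}s^2 - \frac{\bar h}{4}\big)\Big)}
#' \deqn{b = \frac{\bar n}{\bar n - 1}\Big(\bar p(1-\bar p) - \frac{r-1}{r}s^2 - \frac{2\bar n - 1}{4\bar n}\bar h\Big)}
#' \deqn{c = \bar h / 2}
#'
#' @param n1,n2 numbers of called diploid individuals in each population.
#' @param p1,p2 alt-allele frequencies in each population.
#' @param h1,h2 observed heterozygote proportions in each population.
#' @return a `data.frame` with columns `a`, `b`, `c`. Sites where either
#'   population has no called individuals, or where \eqn{\bar n \le 1}
#'   (undefined denominators), get `NA` components.
#' @examples
#' # fixed difference between the populations: theta = 1
#' w <- siteWcComponents(10, 10, 1, 0, 0, 0)
#' w$a / (w$a + w$b + w$c)
#' @export
siteWcComponents <- function(n1, n2, p1, p2, h1, h2) {
    r <- 2
    nbar <- (n1 + n2) / 2
    ok <- n1 >= 1 & n2 >= 1 & nbar > 1
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    a[!ok] <- NA_real_; b[!ok] <- NA_real_; cc[!ok] <- NA_real_
    data.frame(a = a, b = b, c = cc)
}

#' Per-site nucleotide diversity
#'
#' Unbiased per-site diversity \eqn{\pi = 2k(n-k)/(n(n-1))}: the
#' probability that two alleles drawn without replacement from the `n`
#' called alleles differ, with `k` of them being the alternate allele.
#' Sites with fewer than two called alleles contribute 0.
#'
#' @param n called allele counts (2 x called diploids).
#' @param k alt allele counts.
#' @return numeric vector of per-site diversity values in `[0, 1]`.
#' @export
sitePi <- function(n, k) {
    ifelse(n >= 2, 2 * k * (n - k) / (n * (n - 1)), 0)
}

.siteStats <- function(panel) {
    gt <- genotypes(panel)
    pop <- populations(panel)
    perPop <- function(p) {
        sub <- gt[, pop == p, drop = FALSE]
        called <- rowSums(!is.na(sub))
        alt <- rowSums(sub, na.rm = TRUE)
        list(n = called,
             p = ifelse(called > 0, alt / (2 * called), NA_real_),
             h = ifelse(called > 0, rowSums(sub == 1L, na.rm = TRUE) / called,
                        NA_real_),
             pi = sitePi(2 * called, alt))
    }
    f <- perPop("fast"); s <- perPop("slow")
    wc <- siteWcComponents(f$n, s$n, f$p, s$p, f$h, s$h)
    rr <- rowRanges(panel)
    data.frame(chrom = as.character(seqnames(rr)), pos = start(rr),
               a = wc$a, b = wc$b, c = wc$c,
               pi_fast = f$pi, pi_slow = s$pi)
}

#' Windowed FST and nucleotide diversity
#'
#' Aggregates per-site Weir-Cockerham components and per-site diversity
#' over sliding windows (20 kb window, 10 kb step by default). Windows
#' start at position 1 on the step lattice; only full-length windows are
#' emitted (a trailing partial window is dropped). Window FST is the
#' ratio of sums \eqn{\sum a / \sum(a+b+c)}; window diversity is the sum
#' of per-site \eqn{\pi} divided by the window length in bp, so
#' monomorphic and unsampled positions contribute zero. Windows holding
#' fewer than `minSnps` SNPs are excluded (strictly fewer: a window with
#' exactly `minSnps` is retained). A window whose component sum is zero
#' gets `NA` FST and is ignored by the downstream ranking.
#'
#' @param panel a (typically filtered) [PopulationPanel-class]. Chromosome
#'   lengths are taken from `seqlengths(rowRanges(panel))`; chromosomes
#'   with unknown length extend to the last observed SNP.
#' @param window window size in bp.
#' @param step step size in bp.
#' @param minSnps minimum SNP count for a window to be retained.
#' @return a `data.frame` with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `n_snps`, `fst`, `pi_fast`, `pi_slow`, one row per
#'   retained window.
#' @export
windowStats <- function(panel, window = 20000L, step = 10000L,
                        minSnps = 10L) {
    stopifnot(is(panel, "PopulationPanel"), window > 0, step > 0)
    ss <- .siteStats(panel)
    lens <- seqlengths(rowRanges(panel))
    out <- list()
    for (ch in unique(ss$chrom)) {
        L <- lens[[ch]]
        if (is.na(L)) L <- max(ss$pos[ss$chrom == ch])
        if (L < window) next
        starts <- seq.int(1L, L - window + 1L, by = step)
        win <- IRanges(starts, width = window)
        sub <- ss[ss$chrom == ch, , drop = FALSE]
        hits <- findOverlaps(IRanges(sub$pos, width = 1L), win)
        grp <- factor(S4Vectors::subjectHits(hits), levels = seq_along(win))
        idx <- S4Vectors::queryHits(hits)
        sumBy <- function(v)
            as.vector(tapply(v[idx], grp, sum, na.rm = TRUE, default = 0))
        nSnps <- tabulate(S4Vectors::subjectHits(hits), nbins = length(win))
        # components can be NA at sites with a fully-missing population;
        # those sites are skipped within the window sums
        sumA <- sumBy(sub$a); sumB <- sumBy(sub$b); sumC <- sumBy(sub$c)
        denom <- sumA + sumB + sumC
        fst <- ifelse(denom != 0, sumA / denom, NA_real_)
        out[[ch]] <- data.frame(
            chrom = ch, start = starts, end = starts + window - 1L,
            n_snps = nSnps, fst = fst,
            pi_fast = sumBy(sub$pi_fast) / window,
            pi_slow = sumBy(sub$pi_slow) / window)
    }
    if (!length(out))
        stop("no chromosome is long enough for a full window")
    res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
    res[res$n_snps >= minSnps, , drop = FALSE]
}
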