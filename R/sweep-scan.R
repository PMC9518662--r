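#' Z-transform window FST values
#'
#' Standardizes windowed FST to zero mean and unit sample standard
#' deviation (n-1 denominator) across all retained windows, genome-wide.
#' Both focal scans share this one transform.
#'
#' @param fst numeric vector of window FST values (no `NA`s).
#' @return numeric vector of Z scores.
#' @export
zTransform <- function(fst) {
    fst <- as.numeric(fst)
    if (anyNA(fst)) stop("undefined FST values must be dropped before the Z-transform")
    if (length(fst) < 2L) stop("need at least two windows to standardize")
    s <- stats::sd(fst)
    if (s == 0) stop("degenerate FST distribution: zero spread across windows")
    (fst - mean(fst)) / s
}

#' Focal log2 diversity ratio
#'
#' \eqn{\log_2((\pi_{focal} + \epsilon)/(\pi_{other} + \epsilon))} with a
#' per-bp pseudocount \eqn{\epsilon = 10^{-8}} so windows where the focal
#' population has lost all diversity — the strongest sweep candidates —
#' stay finite and rank at the bottom instead of dropping out. A sweep in
#' the focal population drives this ratio strongly negative.
#'
#' @param piFocal,piOther per-bp window diversity of the focal and the
#'   other population.
#' @param eps pseudocount added to both terms.
#' @return numeric vector of log2 ratios.
#' @export
log2PiRatio <- function(piFocal, piOther, eps = 1e-8) {
    log2((piFocal + eps) / (piOther + eps))
}

#' Merge selected windows into candidate regions
#'
#' Overlapping or book-ended selected windows on the same chromosome are
#' merged into maximal candidate regions; each region carries the number
#' of windows it absorbed and its extreme scores.
#'
#' @param windows `data.frame` of selected windows with columns `chrom`,
#'   `start`, `end` and optionally `z` and `log2_ratio`.
#' @param focal focal population label stored on the regions.
#' @return `GRanges` of disjoint regions, sorted, with metadata columns
#'   `n_windows`, `max_z`, `min_ratio`, `focal`.
#' @export
mergeRegions <- function(windows, focal = NA_character_) {
    if (nrow(windows) == 0L)
        return(GRanges(n_windows = integer(0), max_z = numeric(0),
                       min_ratio = numeric(0), focal = character(0)))
    gr <- GRanges(windows$chrom, IRanges(windows$start, windows$end))
    reg <- reduce(sort(gr), min.gapwidth = 1L)
    hits <- findOverlaps(gr, reg)
    grp <- factor(S4Vectors::subjectHits(hits), levels = seq_along(reg))
    reg$n_windows <- as.vector(table(grp))
    reg$max_z <- if (!is.null(windows$z))
        as.vector(tapply(windows$z[S4Vectors::queryHits(hits)], grp, max))
        else NA_real_
    reg$min_ratio <- if (!is.null(windows$log2_ratio))
        as.vector(tapply(windows$log2_ratio[S4Vectors::queryHits(hits)],
                         grp, min))
        else NA_real_
    reg$focal <- focal
    reg
}

#' Joint-quantile selection of sweep-candidate windows
#'
#' Implements the joint outlier rule: a retained window is a candidate
#' for a sweep in the focal population when it lies simultaneously in the
#' top tail of Z-transformed FST (at or above the `fstQuantile` empirical
#' percentile, 95th by default) and in the bottom tail of the focal log2
#' diversity ratio (at or below the `ratioQuantile` percentile, 5th by
#' default). Quantiles use linear interpolation between order statistics
#' and ties at a threshold are included, so the selection is reproducible.
#' Selected windows are merged into candidate regions.
#'
#' @param windows the `data.frame` returned by [windowStats()].
#' @param focal `"fast"` or `"slow"`: which population the scan looks for
#'   sweeps in (its diversity goes in the ratio's numerator).
#' @param fstQuantile upper-tail probability cutoff for Z-FST.
#' @param ratioQuantile lower-tail probability cutoff for the ratio.
#' @return a [ScanResult-class].
#' @examples
#' sw <- GRanges("chr1", IRanges(5e5, 6e5), focal = "fast", strength = 1)
#' sim <- simulatePanel(SimConfig(sweepRegions = sw, seed = 11L))
#' win <- windowStats(applySiteFilters(sim$panel))
#' selectCandidates(win, focal = "fast")
#' @export
selectCandidates <- function(windows, focal = c("fast", "slow"),
                             fstQuantile = 0.95, ratioQuantile = 0.05) {
    focal <- match.arg(focal)
    stopifnot(fstQuantile > 0, fstQuantile <= 1,
              ratioQuantile >= 0, ratioQuantile < 1)
    windows <- windows[!is.na(windows$fst), , drop = FALSE]
    if (nrow(windows) < 20L)
        stop("fewer than 20 windows with defined FST; ",
             "empirical tail quantiles would be meaningless")
    windows$z <- zTransform(windows$fst)
    windows$log2_ratio <- if (focal == "fast")
        log2PiRatio(windows$pi_fast, windows$pi_slow)
    else
        log2PiRatio(windows$pi_slow, windows$pi_fast)
    zThr <- unname(stats::quantile(windows$z, fstQuantile, type = 7))
    rThr <- unname(stats::quantile(windows$log2_ratio, ratioQuantile,
                                   type = 7))
    sel <- windows$z >= zThr & windows$log2_ratio <= rThr
    selWin <- windows[sel, , drop = FALSE]
    if (nrow(selWin) == 0L)
        warning("no window falls in both tails; empty result")
    new("ScanResult", focal = focal, zThreshold = zThr,
        ratioThreshold = rThr, windows = selWin,
        regions = mergeRegions(selWin, focal))
}

#' Write candidate regions as BED
#'
#' Regions are converted from the internal 1-based inclusive coordinates
#' to BED's 0-based half-open convention; the score column carries the
#' region's maximum Z-FST.
#'
#' @param scan a [ScanResult-class].
#' @param path output BED path.
#' @return invisibly, the path.
#' @export
writeRegionsBed <- function(scan, path) {
    reg <- candidateRegions(scan)
    if (!length(reg)) {
        file.create(path)
        return(invisible(path))
    }
    df <- data.frame(chrom = as.character(seqnames(reg)),
                     start = start(reg) - 1L, end = end(reg),
                     name = sprintf("%s_sweep_%03d", scan@focal,
                                    seq_along(reg)),
                     score = round(reg$max_z, 4), strand = ".")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
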