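#' Population-level SNP filtering
#'
#' Applies the conventional resequencing-panel site filters with strict
#' inequalities throughout: genotypes with quality `GQ <= gqMin` are set
#' missing first, then a site is retained only if its call rate (fraction
#' of non-missing genotypes over all samples) is strictly greater than
#' `callRateMin` and its minor allele frequency, computed on alleles
#' pooled across both populations, is strictly greater than `mafMin`.
#' Masking precedes the site-level rules so a low-confidence genotype can
#' never rescue a site's call rate or shift its MAF.
#'
#' Exact-boundary sites are removed: `MAF = 0.05` fails `MAF > 0.05`,
#' a 0.9 call rate fails `> 0.9`, and a genotype at `GQ = 10` is masked
#' by `GQ > 10`.
#'
#' The filter is idempotent and monotone: re-applying the same thresholds
#' changes nothing, and raising any threshold can only shrink the
#' retained set.
#'
#' @param panel a [PopulationPanel-class].
#' @param gqMin genotype-quality threshold; genotypes with `GQ <= gqMin`
#'   are masked (default 10).
#' @param mafMin minor-allele-frequency threshold, strict (default 0.05).
#' @param callRateMin call-rate threshold, strict (default 0.9).
#' @param perPopulation if `TRUE`, the call-rate rule must hold within
#'   each population separately instead of on the pooled samples.
#' @return the filtered [PopulationPanel-class]; the removal counts are
#'   attached as `filterReport(panel)` with fields `sitesIn`,
#'   `genotypesMaskedGQ`, `removedCallRate`, `removedMAF`, `sitesKept`.
#'   A removed site is attributed to the first failing rule in the order
#'   call rate, then MAF.
#' @examples
#' sim <- simulatePanel(SimConfig(chromLengths = c(chr1 = 1e5), seed = 1L))
#' flt <- applySiteFilters(sim$panel)
#' filterReport(flt)
#' @export
applySiteFilters <- function(panel, gqMin = 10, mafMin = 0.05,
                             callRateMin = 0.9, perPopulation = FALSE) {
    stopifnot(is(panel, "PopulationPanel"),
              gqMin >= 0, mafMin >= 0, mafMin < 0.5,
              callRateMin >= 0, callRateMin <= 1)
    gt <- genotypes(panel)
    gq <- genoQual(panel)
    mask <- !is.na(gt) & !is.na(gq) & gq <= gqMin
    gt[mask] <- NA_integer_
    gq[mask] <- NA_integer_

    called <- rowSums(!is.na(gt))
    callRate <- called / ncol(gt)
    if (perPopulation) {
        pop <- populations(panel)
        crPop <- vapply(c("fast", "slow"), function(p) {
            sub <- gt[, pop == p, drop = FALSE]
            rowSums(!is.na(sub)) / ncol(sub)
        }, numeric(nrow(gt)))
        crOK <- crPop[, 1] > callRateMin & crPop[, 2] > callRateMin
    } else {
        crOK <- callRate > callRateMin
    }
    altCount <- rowSums(gt, na.rm = TRUE)
    p <- ifelse(called > 0, altCount / (2 * called), NA_real_)
    maf <- pmin(p, 1 - p)
    mafOK <- !is.na(maf) & maf > mafMin

    keep <- crOK & mafOK
    report <- list(
        sitesIn = nrow(gt),
        genotypesMaskedGQ = sum(mask),
        removedCallRate = sum(!crOK),
        removedMAF = sum(crOK & !mafOK),
        sitesKept = sum(keep),
        thresholds = list(gqMin = gqMin, mafMin = mafMin,
                          callRateMin = callRateMin,
                          perPopulation = perPopulation))
    if (!any(keep))
        stop("no sites survive the filters; review gqMin/mafMin/callRateMin ",
             "against the panel's depth and diversity")
    out <- PopulationPanel(gt[keep, , drop = FALSE], gq[keep, , drop = FALSE],
                           rowRanges(panel)[keep], populations(panel))
    metadata(out)$filterReport <- report
    out
}
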