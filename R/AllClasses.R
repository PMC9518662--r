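#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   reduce granges
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths seqlevels seqnames<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges
#'   colData
NULL

#' Simulation settings for a two-population SNP panel
#'
#' `SimConfig` bundles every knob of the Balding-Nichols panel simulator:
#' the two diploid sample sizes, chromosome lengths, expected SNP density,
#' the divergence coefficient \eqn{F} that controls background
#' differentiation, planted sweep regions, and the genotype-level noise
#' rates. Defaults mirror a small two-breed resequencing design: 4 "fast"
#' versus 10 "slow" diploids on a 2 Mb chromosome at one SNP per kb with
#' moderate background divergence (\eqn{F = 0.1}).
#'
#' @slot nFast,nSlow diploid individual counts per population.
#' @slot chromLengths named numeric vector of chromosome lengths (bp).
#' @slot snpDensity expected SNPs per bp.
#' @slot divergenceF Balding-Nichols divergence parameter in (0, 1).
#' @slot sweepRegions `GRanges` with metadata columns `focal`
#'   (`"fast"`/`"slow"`) and `strength` in (0, 1].
#' @slot missingRate probability that a genotype call is missing.
#' @slot lowGqRate probability that a called genotype gets quality 5
#'   (below the conventional GQ > 10 filter) instead of 99.
#' @slot seed integer RNG seed; identical seed and settings give
#'   bit-identical panels.
#'
#' @seealso [simulatePanel()]
#' @export
setClass("SimConfig",
    representation(
        nFast = "integer",
        nSlow = "integer",
        chromLengths = "numeric",
        snpDensity = "numeric",
        divergenceF = "numeric",
        sweepRegions = "GRanges",
        missingRate = "numeric",
        lowGqRate = "numeric",
        seed = "integer"
    )
)

.validSimConfig <- function(object) {
    msg <- character()
    if (object@nFast < 1L || object@nSlow < 1L)
        msg <- c(msg, "both populations need at least one individual")
    if (is.null(names(object@chromLengths)) ||
        anyNA(names(object@chromLengths)) ||
        any(!nzchar(names(object@chromLengths))))
        msg <- c(msg, "chromLengths must be a named vector")
    if (any(object@chromLengths < 20000))
        msg <- c(msg, "every chromosome must hold at least one 20 kb window")
    if (object@snpDensity <= 0 || object@snpDensity > 1)
        msg <- c(msg, "snpDensity must be in (0, 1]")
    if (object@divergenceF <= 0 || object@divergenceF >= 1)
        msg <- c(msg, "divergenceF must lie strictly inside (0, 1)")
    for (p in c("missingRate", "lowGqRate")) {
        v <- slot(object, p)
        if (v < 0 || v > 1) msg <- c(msg, paste(p, "must be in [0, 1]"))
    }
    sw <- object@sweepRegions
    if (length(sw)) {
        if (is.null(sw$focal) || !all(sw$focal %in% c("fast", "slow")))
            msg <- c(msg, "sweepRegions$focal must be 'fast' or 'slow'")
        if (is.null(sw$strength) || any(sw$strength <= 0 | sw$strength > 1))
            msg <- c(msg, "sweepRegions$strength must be in (0, 1]")
        chr <- as.character(seqnames(sw))
        if (!all(chr %in% names(object@chromLengths)))
            msg <- c(msg, "sweep regions on unknown chromosomes")
        else {
            lens <- object@chromLengths[chr]
            if (any(start(sw) < 1 | end(sw) > lens))
                msg <- c(msg, "sweep regions must lie within their chromosome")
        }
        if (length(reduce(sw, min.gapwidth = 0L)) < length(sw))
            msg <- c(msg, "overlapping sweep regions on the same chromosome are ambiguous")
    }
    if (length(msg)) msg else TRUE
}
setValidity("SimConfig", .validSimConfig)

#' @param nFast,nSlow diploid sample sizes of the fast and slow population.
#' @param chromLengths named numeric vector, chromosome name to length in bp.
#' @param snpDensity expected SNPs per bp.
#' @param divergenceF Balding-Nichols divergence parameter in (0, 1).
#' @param sweepRegions `GRanges` of planted sweeps with `focal` and
#'   `strength` metadata columns; empty for a neutral panel.
#' @param missingRate,lowGqRate genotype-level noise probabilities.
#' @param seed integer RNG seed.
#' @rdname SimConfig-class
#' @examples
#' cfg <- SimConfig(seed = 7L)
#' cfg
#' @export
SimConfig <- function(nFast = 4L, nSlow = 10L,
                      chromLengths = c(chr1 = 2e6),
                      snpDensity = 1e-3, divergenceF = 0.1,
                      sweepRegions = GRanges(),
                      missingRate = 0.02, lowGqRate = 0.02,
                      seed = 1L) {
    new("SimConfig",
        nFast = as.integer(nFast), nSlow = as.integer(nSlow),
        chromLengths = chromLengths, snpDensity = snpDensity,
        divergenceF = divergenceF, sweepRegions = sweepRegions,
        missingRate = missingRate, lowGqRate = lowGqRate,
        seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nFast, "fast +", object@nSlow, "slow diploids\n")
    cat("  chromosomes:", paste0(names(object@chromLengths), " (",
        format(object@chromLengths, big.mark = ",", trim = TRUE), " bp)",
        collapse = ", "), "\n")
    cat("  snpDensity:", object@snpDensity,
        " divergenceF:", object@divergenceF, "\n")
    cat("  planted sweeps:", length(object@sweepRegions), "\n")
    cat("  missingRate:", object@missingRate,
        " lowGqRate:", object@lowGqRate, " seed:", object@seed, "\n")
})

#' Two-population diploid SNP panel
#'
#' `PopulationPanel` extends `RangedSummarizedExperiment`: rows are
#' biallelic SNP sites (a `GRanges` with `ref`/`alt` metadata columns),
#' columns are diploid samples, and two assays hold the alt-allele dosage
#' (`"GT"`, values 0/1/2 with `NA` for missing calls) and the per-genotype
#' Phred-scaled quality (`"GQ"`). Sample population labels
#' (`"fast"`/`"slow"`) live in `colData(x)$population`.
#'
#' Construct one with [PopulationPanel()], [simulatePanel()] or
#' [loadPanel()].
#'
#' @seealso [applySiteFilters()], [windowStats()]
#' @export
setClass("PopulationPanel", contains = "RangedSummarizedExperiment")

.validPopulationPanel <- function(object) {
    msg <- character()
    if (!all(c("GT", "GQ") %in% names(assays(object))))
        msg <- c(msg, "assays 'GT' and 'GQ' are required")
    if (!"population" %in% names(colData(object)))
        msg <- c(msg, "colData must carry a 'population' column")
    else {
        pop <- colData(object)$population
        if (!all(pop %in% c("fast", "slow")))
            msg <- c(msg, "population labels must be 'fast' or 'slow'")
        else if (!all(c("fast", "slow") %in% pop))
            msg <- c(msg, "both populations must be non-empty")
    }
    rr <- rowRanges(object)
    if (length(rr)) {
        if (is.null(rr$ref) || is.null(rr$alt))
            msg <- c(msg, "rowRanges need 'ref' and 'alt' metadata columns")
        else if (any(nchar(rr$ref) != 1L) || any(nchar(rr$alt) != 1L))
            msg <- c(msg, "only biallelic SNPs (single-base ref/alt) are supported")
        if (any(width(rr) != 1L))
            msg <- c(msg, "sites must be single positions")
        bychr <- split(start(rr), as.character(seqnames(rr)))
        if (any(vapply(bychr, is.unsorted, logical(1), strictly = TRUE)))
            msg <- c(msg, "positions must be strictly increasing within chromosome")
        gt <- assay(object, "GT")
        if (!all(gt %in% c(0L, 1L, 2L, NA)))
            msg <- c(msg, "GT dosages must be 0, 1, 2 or NA")
    }
    if (length(msg)) msg else TRUE
}
setValidity("PopulationPanel", .validPopulationPanel)

#' @param gt integer matrix of alt-allele dosages (sites x samples),
#'   `NA` = missing call.
#' @param gq integer matrix of genotype qualities, same shape as `gt`.
#' @param sites `GRanges` of SNP positions with `ref` and `alt`
#'   metadata columns, one base each.
#' @param population character vector (or factor) of `"fast"`/`"slow"`
#'   labels, one per sample column.
#' @rdname PopulationPanel-class
#' @export
PopulationPanel <- function(gt, gq, sites, population) {
    if (is.null(colnames(gt)))
        colnames(gt) <- sprintf("S%02d", seq_len(ncol(gt)))
    storage.mode(gt) <- "integer"
    storage.mode(gq) <- "integer"
    dimnames(gq) <- dimnames(gt)
    se <- SummarizedExperiment(
        assays = SimpleList(GT = gt, GQ = gq),
        rowRanges = sites,
        colData = DataFrame(population = as.character(population),
                            row.names = colnames(gt)))
    new("PopulationPanel", se)
}

#' @rdname PopulationPanel-class
#' @param x,object a `PopulationPanel`.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname PopulationPanel-class
#' @export
setMethod("genotypes", "PopulationPanel", function(x) assay(x, "GT"))

#' @rdname PopulationPanel-class
#' @export
setGeneric("genoQual", function(x) standardGeneric("genoQual"))

#' @rdname PopulationPanel-class
#' @export
setMethod("genoQual", "PopulationPanel", function(x) assay(x, "GQ"))

#' @rdname PopulationPanel-class
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname PopulationPanel-class
#' @export
setMethod("populations", "PopulationPanel",
    function(x) setNames(colData(x)$population, colnames(x)))

#' @rdname PopulationPanel-class
#' @export
setGeneric("filterReport", function(x) standardGeneric("filterReport"))

#' @rdname PopulationPanel-class
#' @export
setMethod("filterReport", "PopulationPanel",
    function(x) metadata(x)$filterReport)

setMethod("show", "PopulationPanel", function(object) {
    pop <- populations(object)
    cat("PopulationPanel:", nrow(object), "SNP sites x", ncol(object),
        "samples (", sum(pop == "fast"), "fast /", sum(pop == "slow"),
        "slow )\n")
    cat("  chromosomes:", paste(seqlevels(rowRanges(object)),
        collapse = ", "), "\n")
    gt <- genotypes(object)
    if (length(gt))
        cat(sprintf("  missing genotypes: %.2f%%\n", 100 * mean(is.na(gt))))
    fr <- filterReport(object)
    if (!is.null(fr))
        cat("  site filters applied:", fr$sitesKept, "of", fr$sitesIn,
            "sites retained\n")
})

#' Result of a joint-quantile sweep scan
#'
#' Produced by [selectCandidates()]. Holds the focal population, the two
#' empirical thresholds (95th percentile of Z-transformed window FST, 5th
#' percentile of the focal log2 diversity ratio by default), the selected
#' windows with their scores, and the merged candidate regions.
#'
#' @slot focal `"fast"` or `"slow"`.
#' @slot zThreshold,ratioThreshold the empirical quantile cutoffs applied.
#' @slot windows `data.frame` of selected windows with `z` and `log2_ratio`
#'   columns appended.
#' @slot regions `GRanges` of merged candidate regions with metadata
#'   columns `n_windows`, `max_z`, `min_ratio`, `focal`.
#' @export
setClass("ScanResult",
    representation(
        focal = "character",
        zThreshold = "numeric",
        ratioThreshold = "numeric",
        windows = "data.frame",
        regions = "GRanges"
    )
)

#' @rdname ScanResult-class
#' @param x,object a `ScanResult`.
#' @export
setGeneric("candidateRegions", function(x) standardGeneric("candidateRegions"))

#' @rdname ScanResult-class
#' @export
setMethod("candidateRegions", "ScanResult", function(x) x@regions)

#' @rdname ScanResult-class
#' @export
setGeneric("selectedWindows", function(x) standardGeneric("selectedWindows"))

#' @rdname ScanResult-class
#' @export
setMethod("selectedWindows", "ScanResult", function(x) x@windows)

setMethod("show", "ScanResult", function(object) {
    cat("ScanResult (focal =", object@focal, ")\n")
    cat(sprintf("  thresholds: z >= %.4f and log2 ratio <= %.4f\n",
        object@zThreshold, object@ratioThreshold))
    cat("  selected windows:", nrow(object@windows), "\n")
    cat("  candidate regions:", length(object@regions), "\n")
})
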