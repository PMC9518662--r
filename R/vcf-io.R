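#' Write a panel to VCF
#'
#' Emits a minimal sorted VCF 4.2 with `GT` and `GQ` FORMAT fields, one
#' ALT allele per record. Missing genotypes are written as `./.` with a
#' `.` quality. The file round-trips through [loadPanel()] with
#' genotype dosages and qualities preserved.
#'
#' @param panel a [PopulationPanel-class].
#' @param path output path (`.vcf`; VariantAnnotation appends `.gz` when
#'   asked to index, which is not done here).
#' @return invisibly, the path written.
#' @export
writePanelVcf <- function(panel, path) {
    stopifnot(is(panel, "PopulationPanel"))
    if (nrow(panel) == 0L) stop("refusing to write an empty panel")
    gt <- genotypes(panel)
    gq <- genoQual(panel)
    gtStr <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], nrow = nrow(gt),
                    dimnames = dimnames(gt))
    gtStr[is.na(gt)] <- "./."
    rr <- granges(rowRanges(panel))
    hdr <- VariantAnnotation::VCFHeader(
        samples = colnames(panel),
        header = IRanges::DataFrameList(
            META = DataFrame(Value = "VCFv4.2", row.names = "fileformat"),
            FORMAT = DataFrame(
                Number = c("1", "1"), Type = c("String", "Integer"),
                Description = c("Genotype", "Genotype quality"),
                row.names = c("GT", "GQ"))))
    vcf <- VariantAnnotation::VCF(
        rowRanges = rr,
        colData = DataFrame(Samples = seq_len(ncol(panel)),
                            row.names = colnames(panel)),
        fixed = DataFrame(
            REF = Biostrings::DNAStringSet(rowRanges(panel)$ref),
            ALT = Biostrings::DNAStringSetList(
                as.list(rowRanges(panel)$alt)),
            QUAL = rep(NA_real_, nrow(panel)),
            FILTER = rep("PASS", nrow(panel))),
        geno = SimpleList(GT = gtStr, GQ = gq))
    VariantAnnotation::header(vcf) <- hdr
    VariantAnnotation::writeVcf(sort(vcf), path)
    # htslib insists on ##fileformat being the first header line
    lines <- readLines(path)
    ff <- grep("^##fileformat=", lines)
    if (length(ff) && ff[1] != 1L)
        writeLines(c(lines[ff[1]], lines[-ff[1]]), path)
    invisible(path)
}

#' Read a population map
#'
#' Two-column tab-separated file (no header): sample identifier, then
#' population label (`fast` or `slow`).
#'
#' @param path popmap TSV path.
#' @return named character vector, sample to population.
#' @export
readPopmap <- function(path) {
    pm <- utils::read.table(path, header = FALSE, sep = "\t",
                            col.names = c("sample", "population"),
                            colClasses = "character")
    if (anyDuplicated(pm$sample)) stop("duplicated samples in popmap")
    bad <- setdiff(unique(pm$population), c("fast", "slow"))
    if (length(bad))
        stop("unknown population labels in popmap: ",
             paste(bad, collapse = ", "))
    setNames(pm$population, pm$sample)
}

.gtToDosage <- function(gtStr) {
    # diploid GT string -> alt dosage; any missing allele -> NA
    d <- rep(NA_integer_, length(gtStr))
    d[gtStr %in% c("0/0", "0|0")] <- 0L
    d[gtStr %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    d[gtStr %in% c("1/1", "1|1")] <- 2L
    d
}

#' Load a two-population panel from VCF
#'
#' Reads a multi-sample VCF with GT and GQ FORMAT fields and attaches
#' population labels from a popmap file. Non-SNP and multiallelic
#' records are skipped (their count is reported in a message); only
#' biallelic single-nucleotide records survive.
#'
#' @param vcfPath path to a VCF (optionally bgzipped).
#' @param popmap either a path to a two-column popmap TSV or a named
#'   character vector as returned by [readPopmap()].
#' @return a [PopulationPanel-class].
#' @export
loadPanel <- function(vcfPath, popmap) {
    if (is.character(popmap) && length(popmap) == 1L && file.exists(popmap))
        popmap <- readPopmap(popmap)
    vcf <- VariantAnnotation::readVcf(vcfPath)
    samples <- colnames(vcf)
    missing <- setdiff(samples, names(popmap))
    if (length(missing))
        stop("samples absent from popmap: ", paste(missing, collapse = ", "))
    keep <- VariantAnnotation::isSNV(vcf, singleAltOnly = TRUE)
    nSkipped <- sum(!keep)
    if (nSkipped)
        message(nSkipped, " non-SNP/multiallelic record(s) skipped")
    vcf <- vcf[keep]
    if (nrow(vcf) == 0L) stop("no biallelic SNP records in ", vcfPath)
    gtStr <- VariantAnnotation::geno(vcf)$GT
    gt <- matrix(.gtToDosage(gtStr), nrow = nrow(gtStr),
                 dimnames = list(NULL, colnames(gtStr)))
    if (!"GQ" %in% names(VariantAnnotation::geno(vcf)))
        stop("VCF lacks the GQ FORMAT field required for quality filtering")
    gq <- VariantAnnotation::geno(vcf)$GQ
    storage.mode(gq) <- "integer"
    gq[is.na(gt)] <- NA_integer_
    rr <- granges(SummarizedExperiment::rowRanges(vcf))
    names(rr) <- NULL
    rr$ref <- as.character(VariantAnnotation::ref(vcf))
    rr$alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
    ord <- order(as.character(seqnames(rr)), start(rr))
    PopulationPanel(gt[ord, , drop = FALSE], gq[ord, , drop = FALSE],
                    rr[ord], population = unname(popmap[colnames(gt)]))
}
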