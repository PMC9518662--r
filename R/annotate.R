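#' Load gene models from BED or GFF3
#'
#' BED intervals (0-based half-open) are converted to the internal
#' 1-based inclusive convention on import; GFF3 `gene` features are
#' already 1-based inclusive and are taken as-is. Gene identifiers come
#' from the BED name column or the GFF3 `ID`/`gene_id` attribute;
#' duplicated identifiers are an error.
#'
#' @param path a `.bed`, `.gff`, `.gff3` or `.gtf` file.
#' @return `GRanges` with a `gene_id` metadata column.
#' @export
loadGenes <- function(path) {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    if (ext == "bed") {
        gr <- rtracklayer::import(path, format = "BED")
        gid <- gr$name
    } else if (ext %in% c("gff", "gff3", "gtf")) {
        gr <- rtracklayer::import(path)
        if ("type" %in% names(S4Vectors::mcols(gr)))
            gr <- gr[gr$type == "gene"]
        gid <- gr$ID
        if (is.null(gid)) gid <- gr$gene_id
        if (is.null(gid)) gid <- gr$Name
    } else {
        stop("unknown annotation format: ", path)
    }
    if (is.null(gid) || anyNA(gid))
        stop("gene identifiers missing in ", path)
    if (anyDuplicated(gid))
        stop("duplicated gene_id in ", path, ": ",
             paste(unique(gid[duplicated(gid)]), collapse = ", "))
    out <- granges(gr)
    names(out) <- NULL
    out$gene_id <- gid
    out
}

#' Genes overlapped by candidate regions
#'
#' A gene is selected when it overlaps any candidate region by at least
#' `minOverlap` bp (1 by default: a single shared base suffices;
#' adjacency is not overlap). A gene spanning several regions is counted
#' once. Chromosomes present in the regions but absent from the
#' annotation trigger a warning, not an error.
#'
#' @param regions a [ScanResult-class] or a `GRanges` of regions.
#' @param genes `GRanges` of gene models with a `gene_id` column, as
#'   from [loadGenes()].
#' @param minOverlap minimum overlap in bp.
#' @return character vector of unique selected gene identifiers.
#' @export
genesInRegions <- function(regions, genes, minOverlap = 1L) {
    if (is(regions, "ScanResult")) regions <- candidateRegions(regions)
    stopifnot(is(regions, "GRanges"), is(genes, "GRanges"),
              !is.null(genes$gene_id))
    lost <- setdiff(unique(as.character(seqnames(regions))),
                    unique(as.character(seqnames(genes))))
    if (length(lost))
        warning("region chromosome(s) absent from the annotation: ",
                paste(lost, collapse = ", "))
    hits <- suppressWarnings(
        findOverlaps(genes, regions, minoverlap = minOverlap))
    unique(genes$gene_id[S4Vectors::queryHits(hits)])
}

#' Compare two populations' selected gene sets
#'
#' Standard set arithmetic between the focal and the other population's
#' candidate genes: the overlap and the focal-exclusive set (focal minus
#' overlap), with all cardinalities. With 479 focal genes of which 39
#' are shared, 440 genes remain exclusive to the focal population.
#'
#' @param focalGenes,otherGenes character vectors of gene identifiers.
#' @return list with `focal_genes`, `other_genes`, `overlap`,
#'   `focal_exclusive` (character vectors) and `sizes`, a named integer
#'   vector of the four cardinalities.
#' @export
compareGeneSets <- function(focalGenes, otherGenes) {
    focalGenes <- unique(as.character(focalGenes))
    otherGenes <- unique(as.character(otherGenes))
    ov <- intersect(focalGenes, otherGenes)
    ex <- setdiff(focalGenes, ov)
    list(focal_genes = focalGenes, other_genes = otherGenes,
         overlap = ov, focal_exclusive = ex,
         sizes = c(focal = length(focalGenes), other = length(otherGenes),
                   overlap = length(ov), focal_exclusive = length(ex)))
}

#' Per-chromosome distribution of selected genes
#'
#' Counts selected genes per chromosome, in descending order, and flags
#' the top-`k` chromosomes — the usual first look at where a scan's
#' signal concentrates.
#'
#' @param geneIds character vector of selected gene identifiers.
#' @param genes `GRanges` gene models with `gene_id`.
#' @param topK how many leading chromosomes to flag.
#' @return `data.frame` with columns `chrom`, `n_genes`, `top` (logical),
#'   sorted by decreasing count. Counts sum to `length(unique(geneIds))`
#'   for genes present in the annotation.
#' @export
chromosomeDistribution <- function(geneIds, genes, topK = 3L) {
    geneIds <- unique(as.character(geneIds))
    sel <- genes[genes$gene_id %in% geneIds]
    if (!length(sel))
        return(data.frame(chrom = character(0), n_genes = integer(0),
                          top = logical(0)))
    tab <- sort(table(as.character(seqnames(sel))), decreasing = TRUE)
    data.frame(chrom = names(tab), n_genes = as.integer(tab),
               top = seq_along(tab) <= topK, row.names = NULL)
}
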