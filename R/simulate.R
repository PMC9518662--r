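#' Simulate a two-population SNP panel with planted sweeps
#'
#' Draws a diploid biallelic panel under the Balding-Nichols model: each
#' site gets an ancestral allele frequency \eqn{p \sim U(0.05, 0.95)} and
#' each population an own frequency
#' \eqn{p_k \sim Beta(p(1-F)/F,\; (1-p)(1-F)/F)}, so the expected
#' differentiation between the two populations is governed by the single
#' divergence parameter \eqn{F}. Genotypes are Binomial(2, \eqn{p_k})
#' (Hardy-Weinberg within population). Inside a planted sweep region the
#' focal population's frequency is replaced by a near-fixation draw
#' \eqn{1 - s\,u} with \eqn{u \sim U(0, 0.05)} and sweep strength
#' \eqn{s}, mirrored to the 0 side with probability 1/2 — which depresses
#' the focal population's nucleotide diversity and inflates FST there,
#' the signature the downstream scan looks for. Missing calls and
#' low-quality genotypes (GQ 5 instead of 99) are injected at the
#' configured rates.
#'
#' The whole draw is deterministic given `config@seed`.
#'
#' @param config a [SimConfig()].
#' @return a list with elements `panel` (a [PopulationPanel-class]) and
#'   `truth` (list: `regions`, the planted sweep `GRanges`; `siteFreq`, a
#'   `data.frame` of per-site ancestral and population allele frequencies).
#' @examples
#' sim <- simulatePanel(SimConfig(chromLengths = c(chr1 = 1e5), seed = 42L))
#' sim$panel
#' @export
simulatePanel <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    set.seed(config@seed)
    F <- config@divergenceF
    nF <- config@nFast
    nS <- config@nSlow
    chroms <- names(config@chromLengths)

    pos <- list(); chrom <- list(); pAnc <- list(); pFast <- list()
    pSlow <- list()
    for (ch in chroms) {
        L <- config@chromLengths[[ch]]
        nSites <- rbinom(1L, size = as.integer(L), prob = config@snpDensity)
        if (nSites == 0L) next
        x <- sort(sample.int(L, nSites))
        p <- runif(nSites, 0.05, 0.95)
        pf <- rbeta(nSites, p * (1 - F) / F, (1 - p) * (1 - F) / F)
        ps <- rbeta(nSites, p * (1 - F) / F, (1 - p) * (1 - F) / F)
        sw <- config@sweepRegions[seqnames(config@sweepRegions) == ch]
        for (i in seq_along(sw)) {
            idx <- which(x >= start(sw)[i] & x <= end(sw)[i])
            if (!length(idx)) next
            u <- runif(length(idx), 0, 0.05)
            fix <- 1 - sw$strength[i] * u
            fix <- ifelse(runif(length(idx)) < 0.5, 1 - fix, fix)
            if (sw$focal[i] == "fast") pf[idx] <- fix else ps[idx] <- fix
        }
        pos[[ch]] <- x; chrom[[ch]] <- rep(ch, nSites)
        pAnc[[ch]] <- p; pFast[[ch]] <- pf; pSlow[[ch]] <- ps
    }
    pos <- unlist(pos, use.names = FALSE)
    if (is.null(pos) || !length(pos))
        stop("no SNPs simulated; raise snpDensity or chromosome lengths")
    chrom <- unlist(chrom, use.names = FALSE)
    pAnc <- unlist(pAnc, use.names = FALSE)
    pFast <- unlist(pFast, use.names = FALSE)
    pSlow <- unlist(pSlow, use.names = FALSE)
    nsite <- length(pos)

    gtF <- matrix(rbinom(nsite * nF, 2L, rep(pFast, nF)), ncol = nF)
    gtS <- matrix(rbinom(nsite * nS, 2L, rep(pSlow, nS)), ncol = nS)
    gt <- cbind(gtF, gtS)
    colnames(gt) <- c(sprintf("fast%02d", seq_len(nF)),
                      sprintf("slow%02d", seq_len(nS)))
    gq <- matrix(ifelse(runif(length(gt)) < config@lowGqRate, 5L, 99L),
                 nrow = nsite)
    gt[runif(length(gt)) < config@missingRate] <- NA_integer_
    gq[is.na(gt)] <- NA_integer_

    ref <- sample(c("A", "C", "G", "T"), nsite, replace = TRUE)
    alt <- vapply(ref, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    sites <- GRanges(chrom, IRanges(pos, width = 1L),
                     ref = unname(ref), alt = unname(alt),
                     seqlengths = config@chromLengths)
    panel <- PopulationPanel(gt, gq, sites,
        population = c(rep("fast", nF), rep("slow", nS)))
    truth <- list(
        regions = config@sweepRegions,
        siteFreq = data.frame(chrom = chrom, pos = pos, p_anc = pAnc,
                              p_fast = pFast, p_slow = pSlow))
    list(panel = panel, truth = truth)
}

#' Simulate FASTQ read sets with controlled QC violations
#'
#' Writes a Phred+33 FASTQ in which exactly `clean` reads pass every
#' read filter, `adapter` reads contain the adapter motif, `highN` reads
#' carry strictly more than 10% N bases, and `lowQ` reads have strictly
#' more than 50% of bases at quality Q <= 5. Useful as ground truth for
#' [filterReads()]: the filter must recover exactly the `clean` reads.
#'
#' @param path output FASTQ path.
#' @param clean,adapter,highN,lowQ non-negative read counts per class.
#' @param readLength read length in bp (default 100).
#' @param adapterMotif motif embedded in adapter-contaminated reads.
#' @param seed integer RNG seed.
#' @return invisibly, the total number of reads written.
#' @export
simulateReads <- function(path, clean = 10L, adapter = 0L, highN = 0L,
                          lowQ = 0L, readLength = 100L,
                          adapterMotif = "AGATCGGAAGAGC", seed = 1L) {
    counts <- c(clean = clean, adapter = adapter, highN = highN, lowQ = lowQ)
    if (any(counts < 0)) stop("read counts must be non-negative")
    if (readLength < nchar(adapterMotif) + 1L && adapter > 0)
        stop("readLength too short to embed the adapter motif")
    set.seed(seed)
    bases <- c("A", "C", "G", "T")
    randRead <- function() paste(sample(bases, readLength, TRUE),
                                 collapse = "")
    goodQual <- function() intToUtf8(33L + sample(30:40, readLength, TRUE))

    seqs <- character(0); quals <- character(0); ids <- character(0)
    add <- function(s, q, tag, i) {
        seqs <<- c(seqs, s); quals <<- c(quals, q)
        ids <<- c(ids, sprintf("%s_%03d", tag, i))
    }
    for (i in seq_len(clean)) add(randRead(), goodQual(), "clean", i)
    for (i in seq_len(adapter)) {
        s <- randRead()
        at <- sample.int(readLength - nchar(adapterMotif) + 1L, 1L)
        substr(s, at, at + nchar(adapterMotif) - 1L) <- adapterMotif
        add(s, goodQual(), "adapter", i)
    }
    nN <- floor(0.10 * readLength) + 1L   # strictly above the 10% boundary
    for (i in seq_len(highN)) {
        s <- strsplit(randRead(), "")[[1]]
        s[sample.int(readLength, nN)] <- "N"
        add(paste(s, collapse = ""), goodQual(), "highN", i)
    }
    nLow <- floor(0.50 * readLength) + 1L # strictly above the 50% boundary
    for (i in seq_len(lowQ)) {
        q <- 33L + sample(30:40, readLength, TRUE)
        q[sample.int(readLength, nLow)] <- 33L + 2L   # Q = 2 <= 5
        add(randRead(), intToUtf8(q), "lowQ", i)
    }
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- ids
    Biostrings::writeXStringSet(dna, path, format = "fastq",
        qualities = Biostrings::BStringSet(quals))
    invisible(length(seqs))
}

#' Simulate a gene annotation and gene-to-term map
#'
#' Places `nGenes` non-overlapping gene intervals uniformly along the
#' given chromosomes (genes allocated proportionally to chromosome
#' length; within a chromosome the gaps between genes follow a uniform
#' Dirichlet split, so placement is uniform among all non-overlapping
#' configurations) and assigns each gene 1-5 terms drawn from `nTerms`
#' term identifiers. Deterministic given `seed`.
#'
#' @param chromLengths named numeric vector of chromosome lengths (bp).
#' @param nGenes total number of genes to place.
#' @param nTerms number of distinct term identifiers.
#' @param geneLength two-element range the gene lengths are drawn from.
#' @param seed integer RNG seed.
#' @return list with `genes` (a `GRanges` with a `gene_id` column) and
#'   `termMap` (a `data.frame` with columns `gene`, `term`).
#' @export
simulateAnnotation <- function(chromLengths, nGenes, nTerms,
                               geneLength = c(2000L, 20000L), seed = 1L) {
    stopifnot(nGenes >= 0, nTerms >= 1)
    set.seed(seed)
    if (nGenes == 0L)
        return(list(genes = GRanges(seqlengths = chromLengths),
                    termMap = data.frame(gene = character(0),
                                         term = character(0))))
    alloc <- as.vector(table(factor(
        sample(names(chromLengths), nGenes, replace = TRUE,
               prob = chromLengths / sum(chromLengths)),
        levels = names(chromLengths))))
    names(alloc) <- names(chromLengths)
    grl <- list()
    for (ch in names(chromLengths)) {
        k <- alloc[[ch]]
        if (k == 0L) next
        L <- chromLengths[[ch]]
        lens <- sample(seq(geneLength[1], geneLength[2]), k, replace = TRUE)
        slack <- L - sum(lens)
        if (slack < 0)
            stop("nGenes too large for the available chromosome space")
        # uniform non-overlapping placement: split the slack into k+1 gaps
        cuts <- sort(sample.int(slack + 1L, k, replace = TRUE) - 1L)
        gaps <- diff(c(0L, cuts))
        starts <- cumsum(gaps) + cumsum(c(0L, lens[-k])) + 1L
        grl[[ch]] <- GRanges(ch, IRanges(starts, width = lens),
                             seqlengths = chromLengths)
    }
    genes <- sort(do.call(c, unname(grl)))
    genes$gene_id <- sprintf("gene%04d", seq_along(genes))
    terms <- sprintf("T%04d", seq_len(nTerms))
    per <- sample(1:5, length(genes), replace = TRUE)
    termMap <- data.frame(
        gene = rep(genes$gene_id, per),
        term = unlist(lapply(per, function(k) sample(terms, k))))
    list(genes = genes, termMap = termMap)
}
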