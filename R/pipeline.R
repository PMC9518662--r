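#' Assemble a pipeline configuration
#'
#' Collects every stage parameter of the end-to-end scan into one list.
#' Defaults are the conventional values of the scan this package
#' implements: 20 kb windows on a 10 kb step, at least 10 SNPs per
#' window, joint 95%/5% quantile tails, GQ > 10, MAF > 0.05, call rate
#' > 0.9 and enrichment reported at P <= 0.05.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer seed driving every stochastic stage.
#' @param simConfig a [SimConfig()] for the simulation stage; its seed is
#'   overridden by `seed`.
#' @param qc run the read-QC stage on small simulated FASTQ sets.
#' @param nGenes,nTerms size of the simulated annotation.
#' @param window,step,minSnps windowing parameters (bp, bp, count).
#' @param fstQuantile,ratioQuantile joint-tail probabilities.
#' @param gqMin,mafMin,callRateMin site-filter thresholds.
#' @param alpha enrichment significance level.
#' @return a named list of class `sweepscan_config`.
#' @export
pipelineConfig <- function(outDir, seed = 1L,
                           simConfig = SimConfig(),
                           qc = TRUE, nGenes = 100L, nTerms = 20L,
                           window = 20000L, step = 10000L, minSnps = 10L,
                           fstQuantile = 0.95, ratioQuantile = 0.05,
                           gqMin = 10, mafMin = 0.05, callRateMin = 0.9,
                           alpha = 0.05) {
    simConfig@seed <- as.integer(seed)
    structure(list(outDir = outDir, seed = as.integer(seed),
                   simConfig = simConfig, qc = qc,
                   nGenes = as.integer(nGenes), nTerms = as.integer(nTerms),
                   window = window, step = step, minSnps = minSnps,
                   fstQuantile = fstQuantile, ratioQuantile = ratioQuantile,
                   gqMin = gqMin, mafMin = mafMin,
                   callRateMin = callRateMin, alpha = alpha),
              class = "sweepscan_config")
}

#' Run the full simulate-to-enrichment pipeline
#'
#' Executes, in dependency order: panel + annotation simulation, optional
#' read-level QC on per-sample FASTQ sets, VCF write and reload,
#' population site filtering, windowed FST/diversity, the joint-quantile
#' scan for both focal populations, gene annotation of the candidate
#' regions, the between-population gene-set comparison, and term
#' enrichment of each focal gene set. Every output lands in
#' `config$outDir` and is listed, with an md5 checksum, in
#' `manifest.json`; rerunning with an identical configuration and seed
#' reproduces identical checksums.
#'
#' @param config a list from [pipelineConfig()].
#' @return invisibly, the manifest list (`params`, `counts`, `files`,
#'   plus the in-memory `scans`, `geneSets`, `comparison` and
#'   `enrichment` results).
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "sweepscan_config"))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    p <- function(...) file.path(config$outDir, ...)
    counts <- list()

    sim <- simulatePanel(config$simConfig)
    panel <- sim$panel
    counts$sites_simulated <- nrow(panel)
    writePanelVcf(panel, p("panel.vcf"))
    utils::write.table(
        data.frame(sample = colnames(panel), pop = populations(panel)),
        p("popmap.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    truth <- as.data.frame(sim$truth$regions)
    utils::write.table(truth, p("truth_regions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    ann <- simulateAnnotation(config$simConfig@chromLengths,
                              config$nGenes, config$nTerms,
                              seed = config$seed)
    rtracklayer::export(ann$genes, p("genes.bed"), format = "BED")
    utils::write.table(ann$termMap, p("gene2term.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)

    if (isTRUE(config$qc)) {
        qcRows <- lapply(seq_len(ncol(panel)), function(i) {
            fq <- p(sprintf("reads_%s.fastq", colnames(panel)[i]))
            simulateReads(fq, clean = 40L, adapter = 3L, highN = 2L,
                          lowQ = 2L, seed = config$seed + i)
            kept <- filterReads(fq, adapters = "AGATCGGAAGAGC")
            summarizeSample(kept, sampleId = colnames(panel)[i])
        })
        qcTab <- do.call(rbind, qcRows)
        qcTab <- rbind(qcTab, aggregateTable(qcTab))
        utils::write.table(qcTab, p("read_qc.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        counts$qc_samples <- ncol(panel)
    }

    panel2 <- loadPanel(p("panel.vcf"), setNames(populations(panel),
                                                 colnames(panel)))
    rr2 <- rowRanges(panel2)
    GenomeInfoDb::seqlengths(rr2) <-
        config$simConfig@chromLengths[seqlevels(rr2)]
    SummarizedExperiment::rowRanges(panel2) <- rr2
    flt <- applySiteFilters(panel2, gqMin = config$gqMin,
                            mafMin = config$mafMin,
                            callRateMin = config$callRateMin)
    counts$sites_loaded <- nrow(panel2)
    counts$sites_after_filters <- nrow(flt)
    jsonlite::write_json(filterReport(flt), p("filter_report.json"),
                         auto_unbox = TRUE, pretty = TRUE)

    win <- windowStats(flt, window = config$window, step = config$step,
                       minSnps = config$minSnps)
    counts$windows_retained <- nrow(win)
    utils::write.table(
        setNames(win, c("CHROM", "BIN_START", "BIN_END", "N_SNPS",
                        "WEIGHTED_FST", "PI_FAST", "PI_SLOW")),
        p("windows.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

    scans <- list(); geneSets <- list(); enr <- list()
    for (focal in c("fast", "slow")) {
        sc <- selectCandidates(win, focal = focal,
                               fstQuantile = config$fstQuantile,
                               ratioQuantile = config$ratioQuantile)
        scans[[focal]] <- sc
        utils::write.table(selectedWindows(sc),
                           p(sprintf("%s_selected_windows.tsv", focal)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        writeRegionsBed(sc, p(sprintf("%s_regions.bed", focal)))
        counts[[paste0("windows_selected_", focal)]] <-
            nrow(selectedWindows(sc))
        gs <- genesInRegions(sc, ann$genes)
        geneSets[[focal]] <- gs
        writeLines(gs, p(sprintf("%s_genes.txt", focal)))
        dist <- chromosomeDistribution(gs, ann$genes)
        utils::write.table(dist, p(sprintf("%s_gene_chrom_dist.tsv", focal)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        counts[[paste0("genes_", focal)]] <- length(gs)
    }
    cmp <- compareGeneSets(geneSets$fast, geneSets$slow)
    jsonlite::write_json(
        list(sizes = as.list(cmp$sizes), overlap = cmp$overlap,
             focal_exclusive = cmp$focal_exclusive),
        p("gene_set_comparison.json"), auto_unbox = TRUE, pretty = TRUE)

    universe <- ann$genes$gene_id
    tm <- setNames(ann$termMap, c("gene", "term"))
    for (focal in c("fast", "slow")) {
        res <- if (length(geneSets[[focal]]))
            enrich(geneSets[[focal]], universe, tm)
        else data.frame()
        enr[[focal]] <- res
        utils::write.table(res, p(sprintf("%s_enrichment.tsv", focal)),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        if (nrow(res))
            counts[[paste0("terms_significant_", focal)]] <-
                nrow(filterSignificant(res, alpha = config$alpha))
    }

    files <- setdiff(list.files(config$outDir), "manifest.json")
    manifest <- list(
        params = config[setdiff(names(config), c("simConfig", "outDir"))],
        counts = counts,
        files = lapply(setNames(files, files), function(f)
            list(md5 = unname(tools::md5sum(p(f))))))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    manifest$scans <- scans
    manifest$geneSets <- geneSets
    manifest$comparison <- cmp
    manifest$enrichment <- enr
    invisible(manifest)
}
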