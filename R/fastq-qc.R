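#' Classify a single read against the quality filters
#'
#' A read is dropped when, in this priority order, (a) any adapter motif
#' occurs as an exact substring of the sequence, (b) its fraction of N
#' bases is strictly above 10%, or (c) strictly more than 50% of its
#' bases have Phred quality at or below 5. All thresholds are strict, so
#' boundary reads (exactly 10% N, exactly 50% low-quality bases) are
#' kept.
#'
#' @param sequence base string over the alphabet A, C, G, T, N.
#' @param qualities integer vector of Phred qualities, one per base.
#' @param adapters character vector of adapter motifs (may be empty).
#' @return `"keep"`, or the drop reason: `"adapter"`, `"n_content"` or
#'   `"low_quality"`.
#' @export
classifyRead <- function(sequence, qualities, adapters = character(0)) {
    if (!nzchar(sequence)) stop("empty read")
    n <- nchar(sequence)
    if (length(qualities) != n)
        stop("sequence and quality lengths differ")
    if (grepl("[^ACGTN]", sequence)) stop("non-ACGTN symbol in read")
    for (ad in adapters)
        if (grepl(ad, sequence, fixed = TRUE)) return("adapter")
    nN <- n - nchar(gsub("N", "", sequence, fixed = TRUE))
    if (nN / n > 0.10) return("n_content")
    if (mean(qualities <= 5) > 0.50) return("low_quality")
    "keep"
}

.readFastq <- function(path, phredOffset = 33L) {
    dna <- Biostrings::readDNAStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
    quals <- lapply(as.character(S4Vectors::mcols(dna)$qualities),
                    function(q) utf8ToInt(q) - phredOffset)
    list(seqs = as.character(dna), quals = quals, ids = names(dna))
}

#' Filter the reads of one FASTQ file
#'
#' Applies [classifyRead()] to every read. The filter is a partition:
#' every input read is either kept or dropped with exactly one reason.
#'
#' @param path FASTQ path (optionally gzipped), Phred+33 by default.
#' @param adapters character vector of adapter motifs.
#' @param phredOffset quality encoding offset (33 or 64).
#' @return list with `seqs` and `quals` of the kept reads, `rawBases`
#'   (total bases before filtering) and `reasons`, a named integer vector
#'   counting `keep`, `adapter`, `n_content` and `low_quality`.
#' @export
filterReads <- function(path, adapters = character(0), phredOffset = 33L) {
    fq <- .readFastq(path, phredOffset)
    cls <- vapply(seq_along(fq$seqs), function(i)
        classifyRead(fq$seqs[i], fq$quals[[i]], adapters), character(1))
    keep <- cls == "keep"
    reasons <- table(factor(cls,
        levels = c("keep", "adapter", "n_content", "low_quality")))
    list(seqs = fq$seqs[keep], quals = fq$quals[keep],
         rawBases = sum(nchar(fq$seqs)),
         reasons = setNames(as.integer(reasons), names(reasons)))
}

#' Per-sample sequencing summary from kept reads
#'
#' Mirrors the usual per-sample QC table row: clean bases, effective
#' rate, mean Phred-implied error rate, Q20/Q30 base percentages and GC
#' content (G+C among non-N bases). The error rate is the mean per-base
#' error probability \eqn{10^{-Q/10}} expressed as a percent.
#'
#' @param kept the list returned by [filterReads()] (or any list with
#'   `seqs`, `quals` and optionally `rawBases`).
#' @param sampleId sample label for the output row.
#' @param rawBases raw base count before filtering; defaults to
#'   `kept$rawBases`.
#' @return one-row `data.frame` with columns `sample_id`, `raw_bases`,
#'   `clean_bases`, `effective_rate`, `error_rate`, `q20`, `q30`,
#'   `gc_content`.
#' @export
summarizeSample <- function(kept, sampleId = "sample",
                            rawBases = kept$rawBases) {
    if (!length(kept$seqs)) stop("no kept reads to summarize")
    q <- unlist(kept$quals)
    allSeq <- paste(kept$seqs, collapse = "")
    nb <- nchar(allSeq)
    nN <- nb - nchar(gsub("N", "", allSeq, fixed = TRUE))
    nGC <- nb - nchar(gsub("[GC]", "", allSeq))
    if (is.null(rawBases)) rawBases <- nb
    data.frame(
        sample_id = sampleId,
        raw_bases = rawBases,
        clean_bases = nb,
        effective_rate = 100 * nb / rawBases,
        error_rate = mean(10^(-q / 10)) * 100,
        q20 = 100 * mean(q >= 20),
        q30 = 100 * mean(q >= 30),
        gc_content = 100 * nGC / (nb - nN))
}

#' Aggregate per-sample QC rows into a summary row
#'
#' For read-level QC tables (columns `raw_bases`, `clean_bases`, ...),
#' base counts are summed, the overall effective rate is
#' \eqn{100\,\Sigma clean/\Sigma raw}, and the remaining percent columns
#' are unweighted arithmetic means across samples. For alignment QC
#' tables (columns `total_reads`, `mapping_rate`, `average_depth`,
#' coverage columns) every numeric column is an unweighted mean, matching
#' the convention of per-sample summary tables in resequencing reports.
#' Mixing the two kinds in one call is an error.
#'
#' @param records `data.frame` of per-sample rows, either read QC
#'   (from [summarizeSample()] or [readQcTable()]) or alignment QC
#'   (from [alignQcTable()]).
#' @return a one-row `data.frame` of the same kind.
#' @export
aggregateTable <- function(records) {
    stopifnot(is.data.frame(records), nrow(records) >= 1)
    isRead <- all(c("raw_bases", "clean_bases") %in% names(records))
    isAlign <- all(c("total_reads", "mapping_rate") %in% names(records))
    if (isRead == isAlign)
        stop("records must be either read-QC or alignment-QC rows, not a mix")
    if (isRead) {
        data.frame(
            sample_id = "summary",
            raw_bases = sum(records$raw_bases),
            clean_bases = sum(records$clean_bases),
            effective_rate = 100 * sum(records$clean_bases) /
                sum(records$raw_bases),
            error_rate = mean(records$error_rate),
            q20 = mean(records$q20),
            q30 = mean(records$q30),
            gc_content = mean(records$gc_content))
    } else {
        if (any(records$coverage_1x < records$coverage_4x) ||
            any(records$coverage_4x < records$coverage_10x))
            stop("coverage columns must be non-increasing with depth")
        data.frame(
            sample_id = "summary",
            total_reads = mean(records$total_reads),
            mapping_rate = mean(records$mapping_rate),
            average_depth = mean(records$average_depth),
            coverage_1x = mean(records$coverage_1x),
            coverage_4x = mean(records$coverage_4x),
            coverage_10x = mean(records$coverage_10x))
    }
}

#' Packaged per-sample QC tables of the motivating study
#'
#' The package ships, as plain TSV fixtures, the per-sample read-quality
#' and alignment summaries of the 14-horse resequencing panel (4 Abaga
#' "fast" + 10 Wushen "slow" animals) that motivates the pipeline.
#' `readQcTable()` returns the read-level table (raw/clean bases,
#' effective rate, error rate, Q20, Q30, GC); `alignQcTable()` the
#' alignment-level one (total reads, mapping rate, depth, coverage).
#' [aggregateTable()] on these rows reproduces the study's printed
#' totals and averages.
#'
#' @return a `data.frame`, one row per sample.
#' @examples
#' aggregateTable(readQcTable())$clean_bases   # 630,535,376,400 bp
#' @export
readQcTable <- function() {
    utils::read.table(system.file("extdata", "study_read_qc.tsv",
                                  package = "SweepScan"),
                      header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname readQcTable
#' @export
alignQcTable <- function() {
    utils::read.table(system.file("extdata", "study_align_qc.tsv",
                                  package = "SweepScan"),
                      header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
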