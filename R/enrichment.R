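#' Hypergeometric term over-representation test
#'
#' For every term with at least one selected gene, computes the
#' upper-tail hypergeometric probability of drawing at least the observed
#' overlap when `length(selected)` genes are sampled without replacement
#' from the universe: `P(X >= overlap)` with
#' `X ~ Hypergeometric(universe, term size, selected size)`. P-values are
#' Benjamini-Hochberg adjusted across the tested terms and results are
#' sorted by raw p. This is the core computation that gene-ontology and
#' pathway over-representation tools reduce to; database-specific
#' corrections (e.g. transcript-length bias weighting) are deliberately
#' not applied.
#'
#' @param selected character vector of selected gene identifiers; must be
#'   a subset of `universe`.
#' @param universe character vector of all gene identifiers considered.
#' @param termMap `data.frame` with columns `gene` and `term`
#'   (many-to-many). Genes outside the universe are dropped with a
#'   warning.
#' @return `data.frame` with columns `term`, `term_size`, `overlap`,
#'   `selected_size`, `universe_size`, `p_value`, `adj_p`, sorted by
#'   `p_value`.
#' @examples
#' # 20-gene universe, 5-gene term, 10 selected, all 5 term genes hit:
#' # p = choose(15, 5) / choose(20, 10) = 3003/184756
#' uni <- sprintf("g%02d", 1:20)
#' tm <- data.frame(gene = uni[1:5], term = "T1")
#' enrich(uni[1:10], uni, tm)$p_value
#' @export
enrich <- function(selected, universe, termMap) {
    selected <- unique(as.character(selected))
    universe <- unique(as.character(universe))
    if (!length(selected) || !length(universe))
        stop("selected and universe must be non-empty")
    if (!all(selected %in% universe))
        stop("selected genes must be a subset of the universe")
    stopifnot(all(c("gene", "term") %in% names(termMap)))
    termMap <- unique(termMap[, c("gene", "term")])
    out <- !(termMap$gene %in% universe)
    if (any(out)) {
        warning(sum(out), " term-map entries outside the universe dropped")
        termMap <- termMap[!out, , drop = FALSE]
    }
    termSize <- table(termMap$term)
    inSel <- termMap[termMap$gene %in% selected, , drop = FALSE]
    overlap <- table(inSel$term)
    if (!length(overlap))
        return(data.frame(term = character(0), term_size = integer(0),
                          overlap = integer(0), selected_size = integer(0),
                          universe_size = integer(0), p_value = numeric(0),
                          adj_p = numeric(0)))
    terms <- names(overlap)
    m <- as.integer(termSize[terms])
    k <- as.integer(overlap)
    N <- length(universe)
    n <- length(selected)
    p <- stats::phyper(k - 1L, m, N - m, n, lower.tail = FALSE)
    res <- data.frame(term = terms, term_size = m, overlap = k,
                      selected_size = n, universe_size = N,
                      p_value = p,
                      adj_p = stats::p.adjust(p, method = "BH"),
                      row.names = NULL)
    res[order(res$p_value, res$term), , drop = FALSE]
}

#' Keep significant enrichment results
#'
#' Retains terms with p at or below `alpha` (inclusive), on the raw or
#' the BH-adjusted p-value.
#'
#' @param results `data.frame` from [enrich()].
#' @param alpha significance level (default 0.05).
#' @param on `"raw"` (default) or `"adjusted"`.
#' @return the filtered `data.frame`.
#' @export
filterSignificant <- function(results, alpha = 0.05,
                              on = c("raw", "adjusted")) {
    on <- match.arg(on)
    p <- if (on == "raw") results$p_value else results$adj_p
    results[p <= alpha, , drop = FALSE]
}
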