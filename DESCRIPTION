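Package: SweepScan
Title: Selective-Sweep Scans from Windowed FST and Nucleotide Diversity in
    Two-Population SNP Panels
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects candidate selective sweeps between two populations from
    diploid SNP genotypes. Implements read-level quality filtering and
    per-sample sequencing summaries, population-level site filtering (genotype
    quality, minor allele frequency, call rate), per-site Weir-Cockerham FST
    variance components and nucleotide diversity aggregated over sliding
    windows, joint quantile outlier calling on Z-transformed FST and the
    log2 diversity ratio, candidate-region merging, gene annotation by
    interval overlap, and hypergeometric term enrichment. Ships a
    Balding-Nichols two-population simulator with planted sweeps so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    VariantAnnotation,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: PopulationGenetics, SNP, Sequencing, QualityControl,
    GeneSetEnrichment
RoxygenNote: 7.3.3
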