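---
title: "Detecting selective sweeps from windowed FST and nucleotide diversity"
author: "SweepScan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting selective sweeps from windowed FST and nucleotide diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(SweepScan)
  library(GenomicRanges)
})
```

## The problem

When two closed populations of the same species have been bred or have
adapted toward different phenotypes — here the motivating contrast is a
fast steppe horse breed against a slow desert one, resequenced as a small
panel of 4 and 10 diploid animals — positive selection leaves a local
signature: the selected population loses nucleotide diversity around the
swept locus while allele frequencies at that locus pull away from the
other population. SweepScan implements the classical two-signal genome
scan for this situation: windowed Weir–Cockerham FST combined with the
windowed diversity ratio, thresholded at joint empirical quantiles, then
annotated down to candidate genes and enriched against gene–term
mappings. A built-in simulator generates panels with planted sweeps so
that every stage, and the pipeline as a whole, is testable against known
truth.

## The statistics

**Per-site FST components.** For two populations (`r` = 2) with `n1`,
`n2` called diploids, alt-allele frequencies `p1`, `p2` and observed
heterozygote proportions `h1`, `h2`, `siteWcComponents()` computes the
Weir & Cockerham (1984) variance components `a` (among populations), `b`
(among individuals within populations) and `c` (within individuals).
The per-site estimator is θ = a/(a+b+c); a window's FST is the *ratio of
sums* Σa/Σ(a+b+c) over its SNPs, the "weighted" windowed estimator
popularized by VCFtools. Sites where a population has no called
genotypes, or where the mean sample size does not exceed one, are
skipped. Negative windowed values are kept as-is — clamping them would
distort the empirical distribution that the Z-transform standardizes.

**Per-site diversity.** `sitePi()` uses the unbiased pairwise estimator
π = 2k(n−k)/(n(n−1)) over the n called alleles with k alternates, i.e.
the probability that two alleles drawn without replacement differ.
Window diversity divides the per-site sum by the full window length
(20,000 bp), so monomorphic and uncalled positions contribute zero.
A callable-length denominator would need per-base coverage information
that a SNP panel does not carry; this is a known limitation shared with
the standard windowed-π tools.

**Windowing.** Windows are 20 kb with a 10 kb step, anchored at
position 1 on the step lattice, and only full-length windows are kept —
rescaling a trailing partial window would make its π denominator
incomparable. Windows with fewer than 10 SNPs are excluded (strictly
fewer: a 10-SNP window stays). Each interior SNP therefore contributes
to exactly two windows.

**Joint-quantile selection.** `selectCandidates()` Z-transforms window
FST (sample standard deviation, n−1) across all retained windows
genome-wide, computes the focal log2 diversity ratio
log2((π~focal~+ε)/(π~other~+ε)), and selects windows simultaneously at or
above the 95th percentile of Z and at or below the 5th percentile of the
ratio. A sweep in the focal population depresses its own diversity, so
the informative tail of the ratio — with the focal population in the
numerator — is the bottom one. Quantiles interpolate linearly between
order statistics and threshold ties are included, making the selection
deterministic across platforms. Selected windows merge into candidate
regions when they overlap or abut.

**Numerical choices.** The pseudocount ε = 10⁻⁸ per bp is three orders
of magnitude below the smallest meaningful window π (one pair-difference
spread over 20 kb ≈ 10⁻⁵ with these panel sizes), so it never reorders
windows with signal but keeps zero-diversity windows — the strongest
candidates — finite and at the extreme of the ranking. A degenerate FST
distribution (zero spread) or fewer than 20 retained windows aborts the
scan with an explicit error rather than returning meaningless quantiles.

## Site and read filtering

Genotype-level and site-level filters reproduce the conventions of small
resequencing panels, all with *strict* inequalities: genotypes at
GQ ≤ 10 are masked first, then sites must have pooled call rate > 0.9
and pooled minor allele frequency > 0.05. Masking precedes the site
rules so a low-confidence genotype can never rescue a site. MAF pools
both populations, treating the panel as one population sample; a
per-population call-rate variant is available behind
`perPopulation = TRUE`. Boundary cases fall out of the filter: MAF of
exactly 0.05 fails, call rate of exactly 0.9 fails, GQ of exactly 10 is
masked. The filter is idempotent and monotone in its thresholds, and
both properties are under test.

Read-level filtering drops a read that contains an adapter motif (exact
substring match — reads are dropped, not trimmed), has strictly more
than 10% N bases, or has strictly more than 50% of bases at Q ≤ 5, in
that priority order. Per-sample summaries report clean bases, the mean
Phred-implied error probability as a percent, Q20/Q30 base fractions and
GC content among non-N bases. Aggregation over samples sums base counts
(with the overall effective rate recomputed from the summed counts) and
takes unweighted means of the percent columns — the convention that
reproduces the printed summary rows of per-sample QC tables, including
the 14-sample tables shipped with the package (`readQcTable()`,
`alignQcTable()`).

## The simulator: what it emulates and what it does not

`simulatePanel()` draws sites independently: ancestral frequency
p ~ U(0.05, 0.95), population frequencies Beta(p(1−F)/F, (1−p)(1−F)/F)
(the Balding–Nichols model), genotypes Binomial(2, p) under
Hardy–Weinberg. F is interpretable as the expected background FST; the
test suite checks that the realized mean Weir–Cockerham θ over tens of
thousands of neutral sites lands on F. Inside a planted sweep region the
focal population's frequency is replaced by a near-fixation draw
1 − s·u, u ~ U(0, 0.05), mirrored to the 0 side with probability ½ —
sufficient to produce the low-π/high-FST signature the scan targets
without a coalescent machinery. Defaults mirror the motivating design:
4 vs 10 diploids, one 2 Mb chromosome, one SNP per kb in expectation,
F = 0.1. The genotype noise rates (2% missing calls, 2% low-quality
genotypes at GQ 5 vs 99 elsewhere) are typical of filtered resequencing
panels; only the ≤10 / >10 GQ contrast matters downstream, so two
quality levels suffice.

What the simulator deliberately lacks: linkage disequilibrium and
recombination structure (sites are exchangeable), sequencing-error
models beyond quality strings, indels and multiallelic sites, and
demographic history beyond the single divergence parameter.
Consequently, passing sweep-recovery tests demonstrates that the scan
machinery finds the low-π/high-differentiation signature at realistic
panel sizes — not that it is robust to LD-induced autocorrelation of
window statistics or to bottleneck-driven false positives in real
genomes, where neighboring windows are far from independent.

## Annotation and enrichment

Candidate regions map to genes by interval overlap: one shared base
suffices (adjacency does not), strand is ignored, and a gene spanning
several regions counts once. A `minOverlap` argument allows stricter
rules. Gene models load from BED (0-based half-open, converted on
import) or GFF3 (1-based inclusive, `gene` features only). The
between-population comparison is plain set arithmetic — with 479 focal
candidates sharing 39 genes with the other population, 440 remain
focal-exclusive — and the per-chromosome distribution is a descending
count table.

Term enrichment is the upper-tail hypergeometric test
P(X ≥ overlap), X ~ Hypergeom(universe, term size, selected size), with
Benjamini–Hochberg adjustment across tested terms; terms without any
selected gene are not reported. This is the core that gene-ontology and
pathway over-representation tools reduce to; database-specific layers
such as transcript-length bias correction or pathway topology are out of
scope. The default universe is every gene in the supplied annotation,
and significance is reported on the raw p at α = 0.05 (inclusive), with
adjusted-p filtering available. Because the hypergeometric is discrete,
the attained level under a uniform null sits slightly below the nominal
0.05 (around 0.04 for term sizes of a few hundred in a 10,000-gene
universe); the calibration test accounts for this.

## A worked run

```{r pipeline, eval = FALSE}
sw  <- GRanges("chr1", IRanges(500001, 600000), focal = "fast", strength = 1)
cfg <- pipelineConfig(outDir = "sweeprun", seed = 5L,
                      simConfig = SimConfig(sweepRegions = sw))
m <- runPipeline(cfg)
m$counts
candidateRegions(m$scans$fast)
```

The pipeline writes every stage's output (VCF, popmap, QC TSV, window
TSV, per-focal selected windows, BED regions, gene lists, enrichment
tables) plus a `manifest.json` with md5 checksums; identical
configuration and seed reproduce identical checksums, which is also
under test. Both focal scans always run — a sweep can sit in either
population, and the symmetric treatment keeps the comparison honest.

## Problem sizes used in validation

The validation suite works at desk scale, chosen so the full suite runs
in a couple of minutes: sweep-recovery uses 20 replicate panels (2 Mb,
~2,000 SNPs, one planted 100 kb full-strength sweep) plus 20 neutral
panels for the false-positive side; the Weir–Cockerham implementation is
checked against an independent scalar transcription on 1,000 random
parameter draws; windowed π against direct allele-pair enumeration on
100 random 20-site panels; and the enrichment null on 2,000 terms over a
10,000-gene universe. On these conditions the planted sweep is recovered
in ≥ 18/20 replicates and neutral panels select well under 2% of windows
(the joint 5%×5% tails would allow 0.25% under independence; the
positive dependence between high FST and extreme ratios keeps the
realized value under 1%).

## Known limitations

Two populations only; biallelic SNPs only; no haplotype statistics
(iHS, XP-EHH) or composite-likelihood sweep models; empirical quantile
thresholds carry no significance statement — they rank, they do not
test; window π uses the full window length rather than callable sites;
and the simulator's independence across sites means real-data window
counts in the tails will be more dispersed than simulated ones.
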