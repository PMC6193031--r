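---
title: "Classifying multivalent chromatin states and germline gene sets"
author: "multiMark maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying multivalent chromatin states and germline gene sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multiMark)
```

# The analysis

Mature *C. elegans* sperm retain nucleosomes carrying histone
modifications, and the pattern of those modifications reflects germline
transcription: genes expressed only during spermatogenesis carry
*multivalent* marking in sperm — the active marks H3K36me3 (gene bodies)
and H3K4me3 (promoters and, unusually, gene bodies) together with the
Polycomb mark H3K27me3 — while genes expressed in both germlines carry
only active marks and silent genes sit in broad H3K27me3 domains.
`multiMark` implements the downstream computational analysis that
establishes such observations from processed sequencing data: coverage
tracks (bedGraph), fragment intervals (BED), and read-count tables. Read
alignment and peak calling are upstream of this package.

The pipeline has five analytical stages, each exposed as ordinary
functions, plus a synthetic-data generator that makes every stage testable
without downloads.

## Coverage quantification and normalization

**Scaling.** Tracks are scaled so the total autosomal signal equals a
target (default $10^7$, i.e. ten million autosomal reads-equivalent).
The X chromosome is excluded from the reference total because the X:A
ratio differs between X0 sperm and XX oocytes/embryos, but X values are
multiplied by the same factor (`scaleToAutosomalTarget()`).

**Per-gene signal.** `geneMeanCoverage()` computes the mean per-base
signal over the gene body, or over a ±500 bp promoter window for
H3K4me3. Two choices deserve note:

* *mean0 semantics*: uncovered bases count as zero in the denominator.
  The alternative (mean over covered bases only) inflates sparsely
  covered genes and breaks the interpretation of the z-score baseline.
* *strand-aware promoters*: the "gene start" is the TSS, i.e. the higher
  coordinate for minus-strand genes. Whether the original analysis was
  strand-aware is not documented; a strand-naive mode is available via
  `strandAware = FALSE`. H3K4me3 is a promoter mark, so a strand-naive
  window would mis-center half the genes — hence the default.

**Normalization.** Signals are transformed $v \mapsto \log_2(v + 1)$ and
z-scored against autosomal genes:

$$z_g = \frac{v_g - b(\text{autosomal } v)}{\mathrm{sd}(\text{autosomal } v)}$$

The baseline $b$ is the autosomal mean, except for H3K27me3 where it is
the 30th percentile of autosomal gene coverages: H3K27me3 occupies about
two thirds of this genome, so the autosomal *mean* sits inside the marked
mass and is not a sensible zero. The scale is always the sample (n−1)
standard deviation of the autosomal values; with ~20,000 genes the n vs
n−1 choice is negligible, and it is recorded in the table's provenance
along with the baseline value and the quantile method (type 7, linear
interpolation — the method is not documented in the original analysis and
is configurable). Applying a percentile baseline forces exactly that
percentile of autosomal genes below zero, which is an intended property,
not an artifact.

## Quadrant and multivalency classification

`classifyQuadrants()` labels each gene by its (active, repressive)
z-score pair: `active_only`, `repressive_only`, `both`, `neither`, with
the boundary at $z = 0$ — the centered axes of the scatter plots this
reproduces. Ties at the threshold count as unmarked (strict $>$ for
marked), a conservative choice that is tested explicitly. The
multivalency flag is `both` on (H3K36me3, H3K27me3), optionally also
requiring promoter H3K4me3 above threshold. `summarizeClassMarking()`
reports per-gene-set quadrant percentages plus an "either exclusive mark"
aggregate.

## Expression and gene sets

RPKM is computed from HTSeq-style counts as
$\mathrm{count} / (\mathrm{length_{kb}} \times \mathrm{libsize}/10^6)$
using the exonic length of the longest isoform. Genes with RPKM > 15
(strict) are "expressed".

The differential-expression stage (`nbTwoGroupTest()`) is a documented
simplification of the standard negative-binomial GLM machinery:
median-of-ratios size factors; pooled within-group method-of-moments
dispersion estimates shrunk in log space toward a parametric
$a_0 + a_1/\mu$ trend (prior weight equivalent to 10 degrees of freedom);
a Wald test on the log2 ratio of normalized group means with a
delta-method standard error and a half-count mean stabilizer; BH
adjustment over tested genes. All-zero genes are excluded from testing
and reported with `tested = FALSE`. Calibration is part of the test
suite: under a 3-vs-3 null with dispersion 0.1, fewer than 1% of genes
reach FDR < 0.05 (measured: ≤ 0.05%), and a planted 4-fold change at mean
100 is detected with power above 0.8 (measured: ~0.98). When exact
reproduction of published DE calls matters, `importDETable()` loads an
externally produced table instead.

Gene sets follow explicit threshold rules (all exposed in
`setRuleConfig()`):

* **Spermatogenesis-specific**: spermatogenic RPKM > 15 (per male
  genotype), wild-type oogenic RPKM < 1, FDR < 0.05 with
  spermatogenic-high orientation; the final set is the intersection
  across the two male genotypes.
* **Sex-independent**: both RPKMs > 5, FDR > 0.05, |log2FC| < 2,
  intersected across genotypes. The fold-change rule is read as
  $|\log_2 FC| < 2$: a signed reading would admit arbitrarily
  oogenic-biased genes into a "no differential expression" set.
* **Misregulation overlap sets**: FDR < 0.05 means "changed",
  FDR ≥ 0.2 means "not changed", and the indeterminate band between
  them belongs to no set. `buildDEOverlapSets()` derives the
  up-in-both / up-in-parent-only / up-in-sperm-only sets and pairwise
  Venn counts.

RPKM thresholds are applied to the mean RPKM across replicates of a
condition (whether the original used per-replicate or averaged values is
undocumented; `reduce = "median"` and `"all"` are provided).

## MNase occupancy

Fragments shorter than 140 bp are removed (nucleosome-protected material
is retained; length exactly 140 is kept). Remaining fragments are
weighted by $10^7/\text{autosomal fragment count}$ and averaged over
fixed-width windows tiling each chromosome — 150 bp windows every 50 bp
by default, with 500/250, 1000/500, 2000/1000 and 5000/2500 repeats.
Windows overhanging the chromosome end are dropped so all means are
comparable. A window is excluded when it has less than 1 fragment in
*all* samples; such windows mark low-mappability regions. Because the
quoted rule counts fragments, the default exclusion mode uses raw
overlap counts, with a scaled-coverage mode available; the excluded
fraction is reported both window-wise and as the genomic-bp fraction of
the union of excluded windows, since a genome-fraction figure can mean
either. Density summaries and the median X/A ratio are computed over
kept windows only.

## Overlap and shift statistics

`hypergeometricOverlap()` gives the exact upper-tail enrichment p-value
for a set overlap, computed in log space so extreme overlaps
($p < 10^{-300}$) remain reportable via `log10_p`. The universe should
be the genes tested in both comparisons; this is the caller's explicit
choice since the original universe is undocumented.
`mannWhitneyShift()` tests whether a gene set's log2 fold changes are
shifted relative to all genes — the background *includes* the subset by
default, matching the subset-vs-all-genes density-plot comparison, with
a complement mode available. The p-value is exact by enumeration of all
labelings when $n_1+n_2 \le 12$ and otherwise uses the normal
approximation with midranks, tie correction and continuity correction.
The normal tail cannot match a small discrete lattice at relative
precision: at $n_1=n_2=6$ the approximation is within 10% of exact for
p ≳ 0.05 and within 0.01 absolutely below that, which is what the test
suite asserts. `benjaminiHochberg()` is the step-up adjustment, tested
against the textbook definition by brute force.

# The synthetic world

`simConfig()` states the world the analysis assumes; the defaults were
chosen once, from the biology, and the tests then verify that the
pipeline recovers them. What the generator emulates:

* **Genome**: five 1 Mb autosomes plus an X, 200 non-overlapping genes
  per chromosome with intergenic gaps (spans 0.8–2.5 kb, gaps 0.5–2 kb),
  exonic transcript lengths 50–90% of the span.
* **Gene classes** in proportions 0.08 spermatogenesis-specific / 0.10
  oogenesis-enriched / 0.12 sex-independent / 0.70 silent. These mirror
  the relative sizes of the real curated sets (~1300, ~2000, ~2100 genes
  of ~20,000) with everything else silent in germlines. The large silent
  fraction also makes ≥70% of genes H3K27me3-positive, which is the
  regime in which a 30th-percentile baseline lands in the gap below the
  marked mass. Spermatogenesis-specific genes are never planted on the
  X, matching germline X silencing; an explicitly "oogenesis-specific"
  class is *not* planted, since the original analysis could not identify
  a high-confidence set of that kind.
* **ChIP tracks** at 50 bp resolution: uniform background (mean 0.5)
  plus class means under multiplicative gamma noise (shape
  $1/\phi$, mean 1, $\phi = 0.2$) — strictly positive noise whose
  variance scales with the mean, mimicking coverage overdispersion.
  Marked levels are 8 for active marks, 6 for H3K27me3 on multivalent
  genes and 3 for the weaker broad domains over silent genes. In sperm,
  spermatogenesis-specific genes get all three marks (H3K4me3 also over
  the body, level 4); in oocytes/embryos they carry only H3K27me3. All
  X-chromosome signal is halved in sperm.
* **Expression**: NB counts with mean = class rate (counts per kb) ×
  transcript length × a log-normal(0, 0.1) library factor, dispersion
  0.1, three replicates, two male genotypes. Rates (30000/1, 15000/40000,
  15000/15000, 1/1 per kb for the four classes in
  spermatogenic/oogenic germlines) give realistic ~7M-read libraries in
  which silent genes sit far below RPKM 1 and expressed classes far
  above RPKM 15.
* **MNase**: 1M fragments per sample with midpoints uniform outside
  planted zero-coverage deserts (2% of each chromosome in three
  intervals — a *genome* property derived from the seed alone, so all
  samples share it, as mappability is shared in reality).
  Nucleosome-protected lengths are Normal(165, 15) truncated at 140 bp
  and a 10% subnucleosomal admixture is Uniform[100, 140); the
  truncation point makes the subnucleosomal fraction exactly the
  sub-140 bp mass, keeping the 140 bp filter's effect interpretable.
  X fragment density is halved in sperm.

What the generator does **not** emulate: mappability structure beyond
binary deserts, fragment GC or digestion bias, peak shape beyond
promoter-vs-body placement, correlated replicates, batch effects, or an
X-specific transcriptional regime. A green recovery test therefore
establishes that the analysis logic is faithful to its definitions and
recovers planted structure under realistic noise — not that it would be
robust to every artifact of real libraries.

Determinism: every stochastic step derives its own sub-seed from the
config seed, so outputs are bit-for-bit reproducible and independent of
evaluation order; the session RNG state is restored afterwards.

# Numerical and degenerate-input policy

* Coordinates are 0-based half-open on disk (BED/bedGraph) and 1-based
  closed in `GRanges`; conversion happens only in the I/O layer.
* Book-ended equal-value bedGraph intervals are merged on read, so equal
  signals have equal representations; overlapping intervals are a
  record-level error naming the first overlap.
* Windows clipped at chromosome bounds average only in-bounds bases;
  genes on chromosomes absent from a track quantify as 0 with a warning.
* Scaling an already-scaled track, zero autosomal signal, zero autosomal
  standard deviation, empty gene sets after universe intersection, and
  groups with zero samples are all hard errors.
* Quadrant ties at the threshold go to the unmarked side; percentage
  tables always sum to 100 over the universe.
* The z-score is invariant to rescaling all coverages only when the
  pseudo-count is rescaled with them; with the fixed pseudo-count of 1
  the invariance is approximate. This is documented behavior, asserted
  in the tests.

# Limitations

The DE stage approximates, but does not replicate, the published tool's
shrinkage estimators; published gene counts will be matched only
approximately, and `importDETable()` is the exact-compatibility path.
Headline numbers of the motivating study depend on deposited raw data
and alignment, which are outside this package's scope; the acceptance
machinery therefore validates the pipeline against its synthetic world
(oracle equivalence, normalization identities, exact small-sample
statistics, DE calibration, and parameter recovery) rather than against
remote data.
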