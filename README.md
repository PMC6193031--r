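# multiMark

Downstream analysis of gamete and early-embryo epigenome profiling in
*C. elegans*: how are histone modifications distributed over genes in
sperm, oocytes and embryos, and how does that marking relate to germline
transcription? The package is written for computational biologists
working from processed sequencing data — bedGraph coverage tracks
(ChIP-seq), BED fragment intervals (MNase-seq) and read-count tables
(RNA-seq) — and reimplements, as tested and reusable functions, the
analysis stages such studies chain together:

- **Coverage quantification** — scaling of tracks to a fixed total
  autosomal signal (default 10⁷; the X is excluded from the reference
  because X:A ratios differ between X0 sperm and XX embryos), mean
  per-base signal over gene bodies or ±500 bp promoter windows, and
  metagene TSS/TES profiles.
- **Chromatin-state classification** — per-mark normalization
  `z = (log₂(v+1) − baseline) / sd` referenced to autosomal genes, with
  a 30th-percentile baseline for the broad repressive mark H3K27me3;
  quadrant classification of each gene into `active_only`,
  `repressive_only`, `both` (multivalent) or `neither` at the z = 0
  boundary; per-gene-set marking percentages.
- **Expression gene sets** — RPKM
  (`count / (length_kb × libsize/10⁶)`, longest isoform), an expressed
  cutoff of RPKM > 15, a negative-binomial two-group Wald test with BH
  adjustment (median-of-ratios size factors, trend-shrunken
  method-of-moments dispersions), and the explicit rule-based sets:
  spermatogenesis-specific (sperm RPKM > 15 ∧ oogenic RPKM < 1 ∧
  FDR < 0.05, intersected across two male genotypes), sex-independent
  (both RPKM > 5 ∧ FDR > 0.05 ∧ |log₂FC| < 2), and the
  FDR < 0.05 / FDR ≥ 0.2 two-threshold misregulation overlap sets.
- **MNase occupancy** — ≥140 bp fragment filtering, autosome-scaled
  coverage in tiled windows (150/50 up to 5000/2500 bp), exclusion of
  windows with < 1 fragment in all samples, and autosome-vs-X density
  summaries.
- **Statistics** — exact hypergeometric overlap tests (log-space tails),
  Mann–Whitney U shift tests (exact by enumeration for n₁+n₂ ≤ 12), and
  Benjamini–Hochberg adjustment.
- **Synthetic data** — a fully seeded generator
  (`simConfig()`/`simulateGenome()`/`simulateChipTracks()`/
  `simulateExpression()`/`simulateMnase()`) that plants gene classes,
  multivalent marking, class-structured expression, low-mappability
  deserts and halved sperm X dosage, with ground truth for recovery
  testing. `runPipeline()` chains everything and writes a manifest.

See the vignette (`vignettes/multivalent-chromatin-analysis.Rmd`) for
the models, parameter meanings and design decisions.

## Worked example

Simulate a sperm epigenome and classify every gene by its gene-body
H3K36me3 and H3K27me3 state:

```r
library(multiMark)

cfg <- simConfig(seed = 42)
sim <- simulateGenome(cfg)
z <- lapply(c(H3K36me3 = "H3K36me3", H3K27me3 = "H3K27me3"), function(mk) {
  track  <- simulateChipTracks(sim$genes, sim$truth, cfg, "sperm", mk)
  scaled <- scaleToAutosomalTarget(track)          # 10M autosomal target
  zscoreAgainstAutosomes(logTransform(
    geneMeanCoverage(scaled, sim$genes, mark = mk)))
})
calls <- classifyQuadrants(z$H3K36me3, z$H3K27me3)
calls
#> QuadrantCall: 1200 genes
#>   active_only       25.2%
#>   repressive_only   51.8%
#>   both               6.6%
#>   neither           16.5%
#>   multivalent      79 genes
```

A quarter of genes carry only the active mark, half only the repressive
mark, and 6.6% carry both — the multivalent state. Split by the planted
gene classes:

```r
classSets <- split(names(plantedClass(sim$truth)), plantedClass(sim$truth))
summarizeClassMarking(calls, classSets)
#>                        set n_used n_dropped active_only repressive_only both  neither either_exclusive
#> 1       oogenesis_enriched    137         0         100         0.00000    0  0.00000        100.00000
#> 2          sex_independent    165         0         100         0.00000    0  0.00000        100.00000
#> 3                   silent    819         0           0        75.82418    0 24.17582         75.82418
#> 4 spermatogenesis_specific     79         0           0         0.00000  100  0.00000          0.00000
```

Every spermatogenesis-specific gene is called multivalent (`both` =
100%), oogenesis and sex-independent genes are uniformly `active_only`,
and silent genes are repressive-only or unmarked — the z = 0 boundary
with the percentile baseline splits the weaker silent-gene H3K27me3
domains, as expected for a threshold placed at the 30th percentile. The
overlap between called-multivalent genes and the planted class is, by
the hypergeometric test:

```r
ss <- names(which(plantedClass(sim$truth) == "spermatogenesis_specific"))
hypergeometricOverlap(geneIds(calls), names(which(isMultivalent(calls))), ss)
#>  Hypergeometric gene-set overlap test
#> data:  overlap 79 of 79 x 79 in universe 1200
#> overlap = 79, N = 1200, K = 79, n = 79, p-value < 2.2e-16
#> alternative hypothesis: greater
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's end-to-end computation from
scratch — simulating the genome, tracks, counts and fragments for the
given seed, then executing scaling, normalization, classification,
gene-set construction, MNase window occupancy and the overlap/shift
statistics — and writes its JSON report to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
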