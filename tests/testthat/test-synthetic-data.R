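## Module tests run on a reduced genome where recovery is not at stake;
## the acceptance suite exercises the full default world.
smallCfg <- function(seed = 7, nFragments = 2e4, ...) {
  simConfig(seed = seed, nAutosomes = 2, chromLength = 2e5,
            nGenesPerChrom = 40, nFragments = nFragments, ...)
}

test_that("the generator is bit-for-bit deterministic under a seed", {
  cfg <- smallCfg(seed = 7)
  a <- simulateGenome(cfg)
  b <- simulateGenome(cfg)
  expect_identical(a$genes, b$genes)
  expect_identical(plantedClass(a$truth), plantedClass(b$truth))
  expect_identical(plantedDeserts(a$truth), plantedDeserts(b$truth))
  t1 <- simulateChipTracks(a$genes, a$truth, cfg, "sperm", "H3K36me3")
  t2 <- simulateChipTracks(b$genes, b$truth, cfg, "sperm", "H3K36me3")
  expect_identical(trackRanges(t1)$score, trackRanges(t2)$score)
  e1 <- simulateExpression(a$genes, a$truth, cfg)
  e2 <- simulateExpression(b$genes, b$truth, cfg)
  expect_identical(SummarizedExperiment::assay(e1, "counts"),
                   SummarizedExperiment::assay(e2, "counts"))
  f1 <- simulateMnase(a$genes, cfg, "sperm")
  f2 <- simulateMnase(b$genes, cfg, "sperm")
  expect_identical(f1, f2)
  ## different replicates differ
  f3 <- simulateMnase(a$genes, cfg, "sperm", replicate = 2)
  expect_false(identical(f1, f3))
})

test_that("genes are non-overlapping and classes follow the proportions", {
  cfg <- smallCfg(seed = 3)
  sim <- simulateGenome(cfg)
  byChrom <- split(IRanges::ranges(sim$genes),
                   as.factor(GenomicRanges::seqnames(sim$genes)))
  for (r in byChrom)
    if (length(r) > 1)
      expect_true(all(BiocGenerics::start(r)[-1] >
                        BiocGenerics::end(r)[-length(r)]))

  ## degenerate proportions: all sex_independent
  cfg1 <- smallCfg(seed = 3, classProportions = c(
    spermatogenesis_specific = 0, oogenesis_enriched = 0,
    sex_independent = 1, silent = 0))
  sim1 <- simulateGenome(cfg1)
  expect_true(all(plantedClass(sim1$truth) == "sex_independent"))

  ## default proportions: autosomal class counts within binomial 99% bounds
  cfg2 <- simConfig(seed = 11, nAutosomes = 5, chromLength = 1e6,
                    nGenesPerChrom = 200)
  sim2 <- simulateGenome(cfg2)
  auto <- names(plantedClass(sim2$truth))[grepl("^chr[IV]+_", names(
    plantedClass(sim2$truth)))]
  cls <- plantedClass(sim2$truth)[auto]
  nAuto <- length(cls)
  p <- cfg2@classProportions
  for (cc in names(p)) {
    lo <- qbinom(0.005, nAuto, p[[cc]])
    hi <- qbinom(0.995, nAuto, p[[cc]])
    expect_gte(sum(cls == cc), lo)
    expect_lte(sum(cls == cc), hi)
  }
  ## no spermatogenesis-specific genes on the X
  xGenes <- grepl("^chrX_", names(plantedClass(sim2$truth)))
  expect_false(any(plantedClass(sim2$truth)[xGenes] ==
                     "spermatogenesis_specific"))
})

test_that("gene density that cannot fit the chromosome is an error", {
  cfg <- simConfig(seed = 1, nAutosomes = 1, chromLength = 5e4,
                   nGenesPerChrom = 100)
  expect_error(simulateGenome(cfg), "cannot fit")
})

test_that("noiseless tracks reproduce the configured class means exactly", {
  cfg <- smallCfg(seed = 5, noiseDispersion = 0, background = 0)
  sim <- simulateGenome(cfg)
  tr <- simulateChipTracks(sim$genes, sim$truth, cfg, "sperm", "H3K36me3")
  tab <- suppressWarnings(geneMeanCoverage(tr, sim$genes))
  cls <- plantedClass(sim$truth)[geneIds(tab)]
  auto <- tab@isAutosomal
  v <- signalMatrix(tab)[, 1]
  mi <- cfg@markIntensity
  m36 <- function(cc) {
    hit <- mi$mean[mi$class == cc & mi$cell_type == "sperm" &
                     mi$mark == "H3K36me3"]
    if (length(hit)) hit else 0
  }
  for (cc in unique(cls))
    expect_equal(unname(v[auto & cls == cc]),
                 rep(m36(cc), sum(auto & cls == cc)))
  ## X signal is halved in sperm
  xActive <- !auto & cls == "sex_independent"
  if (any(xActive))
    expect_equal(unname(v[xActive]),
                 rep(8 * cfg@xPloidyRatioSperm, sum(xActive)))
})

test_that("sperm multivalent marking and embryo repressive-only marking hold", {
  cfg <- smallCfg(seed = 9)
  sim <- simulateGenome(cfg)
  ssGenes <- names(which(plantedClass(sim$truth) ==
                           "spermatogenesis_specific"))
  bgLevel <- cfg@background
  meanOver <- function(cellType, mark) {
    tr <- simulateChipTracks(sim$genes, sim$truth, cfg, cellType, mark)
    tab <- suppressWarnings(geneMeanCoverage(
      tr, sim$genes,
      window = if (mark == "H3K4me3") "promoter" else "gene_body"))
    rowMeans(signalMatrix(tab))[ssGenes]
  }
  ## sperm: all three marks well above background over these genes
  for (mk in c("H3K36me3", "H3K27me3", "H3K4me3"))
    expect_gt(min(meanOver("sperm", mk)), 2 * bgLevel)
  ## embryo: only H3K27me3 above background
  expect_gt(min(meanOver("embryo", "H3K27me3")), 2 * bgLevel)
  expect_lt(max(meanOver("embryo", "H3K36me3")), 2 * bgLevel)
  expect_lt(max(meanOver("embryo", "H3K4me3")), 2 * bgLevel)
  expect_error(simulateChipTracks(sim$genes, sim$truth, cfg, "soma",
                                  "H3K36me3"), "cell type")
  expect_error(simulateChipTracks(sim$genes, sim$truth, cfg, "sperm",
                                  "H3K9me3"), "mark")
})

test_that("class-mean recovery: per-class raw signal within 3 SE of config", {
  cfg <- simConfig(seed = 23)
  sim <- simulateGenome(cfg)
  tr <- simulateChipTracks(sim$genes, sim$truth, cfg, "sperm", "H3K36me3")
  tab <- suppressWarnings(geneMeanCoverage(tr, sim$genes))
  cls <- plantedClass(sim$truth)[geneIds(tab)]
  v <- signalMatrix(tab)[, 1][tab@isAutosomal]
  cl <- cls[tab@isAutosomal]
  for (cc in c("spermatogenesis_specific", "sex_independent")) {
    x <- v[cl == cc] - cfg@background  # subtract mean uniform background
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - 8), 3 * se + 1e-9)  # configured H3K36me3 mean
  }
})

test_that("expression counts follow the planted class structure", {
  cfg <- simConfig(seed = 13)
  sim <- simulateGenome(cfg)
  expr <- computeRPKM(simulateExpression(sim$genes, sim$truth, cfg))
  r <- rpkm(expr)
  cd <- SummarizedExperiment::colData(expr)
  cls <- plantedClass(sim$truth)[rownames(r)]
  spCols <- cd$germline_type == "spermatogenic"
  ooCols <- cd$germline_type == "oogenic"
  ## silent genes: RPKM < 1 in >= 99% of replicates
  expect_gte(mean(r[cls == "silent", ] < 1), 0.99)
  ## oogenesis-enriched genes expressed in BOTH germlines, oogenic-biased
  oe <- cls == "oogenesis_enriched"
  expect_gte(mean(rowMeans(r[oe, spCols]) > 15), 0.99)
  expect_gte(mean(rowMeans(r[oe, ooCols]) > 15), 0.99)
  expect_gt(median(rowMeans(r[oe, ooCols]) / rowMeans(r[oe, spCols])), 1.5)
})

test_that("zero expression dispersion gives Poisson-like counts", {
  cfg <- smallCfg(seed = 17, exprDispersion = 0, nReplicates = 50,
                  libraryFactorSd = 0)
  sim <- simulateGenome(cfg)
  expr <- simulateExpression(sim$genes, sim$truth, cfg)
  cnt <- SummarizedExperiment::assay(expr, "counts")
  cd <- SummarizedExperiment::colData(expr)
  sp <- cnt[, cd$germline_type == "spermatogenic" &
              cd$genotype == "wild_type"]
  mu <- rowMeans(sp)
  vr <- apply(sp, 1, var)
  keep <- mu > 50
  ## variance/mean ratio ~ 1 for Poisson; chi-square bounds at n = 50
  expect_lt(median(abs(vr[keep] / mu[keep] - 1)), 0.3)
})

test_that("MNase fragments respect the length model and X dosage", {
  cfg <- smallCfg(seed = 29, subnucleosomalFraction = 0)
  sim <- simulateGenome(cfg)
  fr <- simulateMnase(sim$genes, cfg, "embryo")
  expect_true(all(BiocGenerics::width(fr) >= 140))

  cfg2 <- smallCfg(seed = 29, subnucleosomalFraction = 0.25)
  fr2 <- simulateMnase(sim$genes, cfg2, "embryo")
  subFrac <- mean(BiocGenerics::width(fr2) < 140)
  expect_lt(abs(subFrac - 0.25), 0.02)
  expect_true(all(BiocGenerics::width(fr2) >= 100))

  ## per-bp X/autosome density: halved in sperm relative to embryo
  cfg3 <- smallCfg(seed = 31, nFragments = 2e5)
  sim3 <- simulateGenome(cfg3)
  dens <- function(cellType) {
    f <- simulateMnase(sim3$genes, cfg3, cellType)
    isX <- as.character(GenomicRanges::seqnames(f)) == "chrX"
    (sum(isX) / 1) / (sum(!isX) / cfg3@nAutosomes)
  }
  ratio <- dens("sperm") / dens("embryo")
  expect_lt(abs(ratio - cfg3@xPloidyRatioSperm), 0.05)
})

test_that("planted deserts carry no fragment midpoints and are shared", {
  cfg <- smallCfg(seed = 37)
  sim <- simulateGenome(cfg)
  des <- plantedDeserts(sim$truth)
  frS <- simulateMnase(sim$genes, cfg, "sperm")
  frE <- simulateMnase(sim$genes, cfg, "embryo")
  mids <- function(f) GenomicRanges::GRanges(
    GenomicRanges::seqnames(f),
    IRanges::IRanges(IRanges::mid(IRanges::ranges(f)), width = 1))
  ## midpoints land outside deserts (1 bp rounding slack at boundaries)
  expect_lt(sum(GenomicRanges::countOverlaps(des, mids(frS))) /
              length(frS), 1e-3)
  expect_lt(sum(GenomicRanges::countOverlaps(des, mids(frE))) /
              length(frE), 1e-3)
})
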