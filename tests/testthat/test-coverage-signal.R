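test_that("autosomal scaling hits the target and rescales the X alike", {
  df <- data.frame(chrom = c("chrI", "chrI", "chrX"),
                   start0 = c(0, 150, 0), end0 = c(150, 300, 100),
                   value = c(2, 4, 5))
  tr <- trackFromDf(df)
  scaled <- scaleToAutosomalTarget(tr, target = 1800)
  ## raw autosomal total is 900 -> factor 2 everywhere, X included
  expect_equal(autosomalTotal(scaled), 1800)
  expect_equal(trackRanges(scaled)$score, c(4, 8, 10))
  expect_equal(scaleState(scaled), "autosome-scaled")
  expect_error(scaleToAutosomalTarget(scaled), "already scaled")

  ## identity when the raw total equals the target
  df2 <- data.frame(chrom = "chrI", start0 = 0, end0 = 1000, value = 1)
  same <- scaleToAutosomalTarget(trackFromDf(df2), target = 1000)
  expect_equal(trackRanges(same)$score, 1)

  ## X-only track cannot be scaled
  dfx <- data.frame(chrom = "chrX", start0 = 0, end0 = 100, value = 1)
  expect_error(scaleToAutosomalTarget(trackFromDf(dfx)), "no autosomal")
})

test_that("gene-body means match the per-base definition", {
  df <- data.frame(chrom = "chrI", start0 = c(0, 150), end0 = c(150, 300),
                   value = c(2, 4))
  tr <- trackFromDf(df)
  genes <- makeGenes("chrI", 100, 200)
  tab <- suppressWarnings(geneMeanCoverage(tr, genes))
  expect_equal(unname(signalMatrix(tab)[, 1]), 3.0)

  ## gene entirely outside covered intervals
  genes2 <- makeGenes("chrI", c(100, 5000), c(200, 6000))
  tab2 <- suppressWarnings(geneMeanCoverage(tr, genes2))
  expect_equal(unname(signalMatrix(tab2)[, 1]), c(3.0, 0))

  ## chromosome absent from track: zero with a warning (the unscaled-track
  ## warning is also expected here)
  genes3 <- makeGenes("chrII", 0, 100)
  expect_warning(expect_warning(tab3 <- geneMeanCoverage(tr, genes3),
                                "unscaled"), "absent")
  expect_equal(unname(signalMatrix(tab3)[, 1]), 0)
})

test_that("promoter windows are strand-aware and clipped", {
  len <- c(chrI = 3000)
  set.seed(11)
  df <- randomTrackDf("chrI", 3000, 30)
  tr <- trackFromDf(df, seqlen = len)
  ## minus-strand gene [100, 200): promoter anchored at coordinate 200
  genes <- makeGenes("chrI", 100, 200, strand = "-", seqlen = len)
  tab <- suppressWarnings(geneMeanCoverage(tr, genes, window = "promoter",
                                           flank = 500))
  expect_equal(unname(signalMatrix(tab)[, 1]),
               bruteMean(df, "chrI", 200 - 500, 200 + 500, 3000))
  ## strand-naive option anchors at the lower coordinate
  tabNaive <- suppressWarnings(geneMeanCoverage(
    tr, genes, window = "promoter", flank = 500, strandAware = FALSE))
  expect_equal(unname(signalMatrix(tabNaive)[, 1]),
               bruteMean(df, "chrI", 100 - 500, 100 + 500, 3000))
})

test_that("interval arithmetic equals per-base brute force on small fixtures", {
  set.seed(101)
  len <- 8000
  for (rep in 1:5) {
    df <- randomTrackDf("chrI", len, 40)
    tr <- trackFromDf(df, seqlen = c(chrI = len))
    s0 <- sort(sample(0:(len - 10), 25))
    e0 <- pmin(s0 + sample(50:900, 25, replace = TRUE), len)
    genes <- makeGenes("chrI", s0, e0,
                       strand = sample(c("+", "-"), 25, replace = TRUE),
                       seqlen = c(chrI = len))
    tab <- suppressWarnings(geneMeanCoverage(tr, genes))
    oracle <- vapply(seq_along(s0), function(i)
      bruteMean(df, "chrI", s0[i], e0[i], len), numeric(1))
    expect_equal(unname(signalMatrix(tab)[, 1]), oracle, tolerance = 1e-12)
  }
})

test_that("scaling equivariance: quantify-then-scale equals scale-then-quantify", {
  set.seed(7)
  df <- randomTrackDf("chrI", 5000, 30)
  tr <- trackFromDf(df, seqlen = c(chrI = 5000))
  genes <- makeGenes("chrI", c(100, 2000), c(900, 2600),
                     seqlen = c(chrI = 5000))
  raw <- suppressWarnings(geneMeanCoverage(tr, genes))
  scaled <- geneMeanCoverage(scaleToAutosomalTarget(tr, 1e7), genes)
  f <- 1e7 / autosomalTotal(tr)
  expect_equal(signalMatrix(scaled), signalMatrix(raw) * f)
})

test_that("metagene profiles are flat on constant tracks and linear in genes", {
  len <- c(chrI = 10000)
  dfc <- data.frame(chrom = "chrI", start0 = 0, end0 = 10000, value = 2.5)
  trc <- trackFromDf(dfc, seqlen = len)
  genes <- makeGenes("chrI", c(3000, 6000), c(4000, 7000),
                     strand = c("+", "-"), seqlen = len)
  prof <- suppressWarnings(metageneProfile(trc, genes, anchor = "TSS"))
  expect_true(all(abs(prof$mean_signal - 2.5) < 1e-12))
  expect_equal(nrow(prof), 2 * 1000 / 50)
  expect_equal(prof$bin_start[1], -1000)
  expect_error(metageneProfile(trc, genes[0], anchor = "TSS"), "empty")

  ## profile of a set = mean of single-gene profiles
  set.seed(3)
  df <- randomTrackDf("chrI", 10000, 50)
  tr <- trackFromDf(df, seqlen = len)
  pAll <- suppressWarnings(metageneProfile(tr, genes, anchor = "TES"))
  p1 <- suppressWarnings(metageneProfile(tr, genes[1], anchor = "TES"))
  p2 <- suppressWarnings(metageneProfile(tr, genes[2], anchor = "TES"))
  expect_equal(pAll$mean_signal, (p1$mean_signal + p2$mean_signal) / 2)
})

test_that("metagene bins match a per-base oracle and reflect under mirroring", {
  len <- 6000
  set.seed(19)
  df <- randomTrackDf("chrI", len, 40)
  tr <- trackFromDf(df, seqlen = c(chrI = len))
  g <- makeGenes("chrI", 2000, 3200, strand = "+", seqlen = c(chrI = len))
  prof <- suppressWarnings(metageneProfile(tr, g, anchor = "TSS",
                                           flank = 500, binWidth = 100))
  oracle <- vapply(seq(-500, 400, by = 100), function(rel)
    bruteMean(df, "chrI", 2000 + rel, 2000 + rel + 100, len), numeric(1))
  expect_equal(prof$mean_signal, oracle, tolerance = 1e-12)

  ## mirrored genome: minus-strand profile equals the plus-strand one
  dfm <- data.frame(chrom = "chrI", start0 = len - df$end0,
                    end0 = len - df$start0, value = df$value)
  trm <- trackFromDf(dfm, seqlen = c(chrI = len))
  gm <- makeGenes("chrI", len - 3200, len - 2000, strand = "-",
                  seqlen = c(chrI = len))
  profM <- suppressWarnings(metageneProfile(trm, gm, anchor = "TSS",
                                            flank = 500, binWidth = 100))
  expect_equal(profM$mean_signal, prof$mean_signal, tolerance = 1e-12)
})
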