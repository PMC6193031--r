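## fixture: ExpressionTable with directly planted RPKM values
rpkmFixture <- function(rpkmMat, germline, genotype) {
  cnt <- matrix(1L, nrow(rpkmMat), ncol(rpkmMat), dimnames = dimnames(rpkmMat))
  si <- data.frame(germline_type = germline, genotype = genotype,
                   replicate = ave(seq_along(germline),
                                   paste(germline, genotype), FUN = seq_along))
  rownames(si) <- colnames(cnt)
  expr <- ExpressionTable(cnt, si)
  SummarizedExperiment::assay(expr, "rpkm", withDimnames = FALSE) <- rpkmMat
  expr
}

deFixture <- function(genes, lfc, fdr) {
  new("DEResult",
      table = data.frame(gene = genes, base_mean = 100,
                         log2_fold_change = lfc, p_value = fdr, fdr = fdr,
                         tested = TRUE),
      provenance = list(source = "fixture"))
}

test_that("RPKM follows counts / (length_kb x library_millions)", {
  cnt <- matrix(c(150, 850000 - 150, 30, 2e6 - 30), 2, 2,
                dimnames = list(c("gA", "filler"), c("s1", "s2")))
  ## pad the filler so column totals are exactly 1e6 and 2e6
  cnt["filler", "s1"] <- 1e6 - 150
  si <- data.frame(germline_type = c("spermatogenic", "oogenic"),
                   genotype = "wild_type", replicate = c(1, 1))
  rownames(si) <- colnames(cnt)
  expr <- ExpressionTable(cnt, si)
  lengths <- c(gA = 1000, filler = 2000)
  r <- rpkm(computeRPKM(expr, lengths))
  expect_equal(r["gA", "s1"], 150)         # 150 / (1 kb x 1 M)
  lengths2 <- c(gA = 2000, filler = 2000)
  r2 <- rpkm(computeRPKM(expr, lengths2))
  expect_equal(r2["gA", "s2"], 7.5)        # 30 / (2 kb x 2 M)

  ## invariance under uniform per-sample count scaling
  expr3 <- ExpressionTable(cnt * 3L, si)
  expect_equal(rpkm(computeRPKM(expr3, lengths)), rpkm(computeRPKM(expr, lengths)))

  expect_error(computeRPKM(expr, c(gA = 1000)), "filler")
  cnt0 <- cnt; cnt0[, 2] <- 0L
  expect_error(computeRPKM(ExpressionTable(cnt0, si), lengths), "zero column")
})

test_that("expressed calls use a strict RPKM threshold", {
  r <- matrix(c(15.01, 15, 0), 3, 1,
              dimnames = list(c("a", "b", "c"), "s1"))
  expr <- rpkmFixture(r, "spermatogenic", "wild_type")
  out <- callExpressed(expr)
  expect_identical(geneIds(out[[1]]), "a")
})

test_that("the NB two-group test is symmetric, guarded and calibrated", {
  set.seed(1)
  cnt <- matrix(rnbinom(600 * 6, mu = 100, size = 10), 600, 6,
                dimnames = list(paste0("g", 1:600), paste0("s", 1:6)))
  cnt[1, ] <- 0L  # all-zero gene is excluded from testing
  ## identical groups (a permutation of the same columns)
  de <- nbTwoGroupTest(cnt, c(1, 2, 3), c(3, 1, 2))
  tab <- deTable(de)
  expect_equal(tab$log2_fold_change[tab$tested], rep(0, 599))
  expect_equal(tab$p_value[tab$tested], rep(1, 599))
  expect_false(tab$tested[1])
  expect_true(is.na(tab$fdr[1]))
  expect_error(nbTwoGroupTest(cnt, integer(0), 4:6), "at least one")
  expect_warning(nbTwoGroupTest(cnt[1:50, ], 1, 2:3), "single-replicate")

  ## planted signal is found, null genes mostly are not
  set.seed(2)
  mu <- rep(100, 500)
  g1 <- sapply(1:3, function(i) rnbinom(500, mu = mu, size = 10))
  mu2 <- mu; mu2[1:50] <- 400
  g2 <- sapply(1:3, function(i) rnbinom(500, mu = mu2, size = 10))
  cnt2 <- cbind(g1, g2)
  rownames(cnt2) <- paste0("g", 1:500)
  colnames(cnt2) <- paste0("s", 1:6)
  tab2 <- deTable(nbTwoGroupTest(cnt2, 1:3, 4:6))
  expect_gt(mean(tab2$fdr[1:50] < 0.05), 0.8)     # power
  expect_lt(mean(tab2$fdr[51:500] < 0.05), 0.02)  # specificity
  expect_gt(mean(tab2$log2_fold_change[1:50]), 1.5)  # oriented B-high
})

test_that("the NB test agrees with an established NB-GLM implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(33)
  n <- 400
  mu <- exp(runif(n, log(30), log(1000)))
  fc <- rep(1, n); fc[1:40] <- 3
  cnt <- cbind(sapply(1:3, function(i) rnbinom(n, mu = mu, size = 8)),
               sapply(1:3, function(i) rnbinom(n, mu = mu * fc, size = 8)))
  rownames(cnt) <- paste0("g", 1:n)
  colnames(cnt) <- paste0("s", 1:6)
  mine <- deTable(nbTwoGroupTest(cnt, 1:3, 4:6))
  dds <- DESeq2::DESeqDataSetFromMatrix(
    cnt, data.frame(group = factor(rep(c("A", "B"), each = 3))), ~group)
  res <- DESeq2::results(suppressMessages(DESeq2::DESeq(dds, quiet = TRUE)))
  ok <- mine$tested & !is.na(res$padj)
  expect_gt(cor(mine$log2_fold_change[ok], res$log2FoldChange[ok]), 0.95)
  myHits <- which(mine$fdr < 0.05)
  dsHits <- which(res$padj < 0.05)
  jac <- length(intersect(myHits, dsHits)) /
    length(union(myHits, dsHits))
  expect_gt(jac, 0.6)
})

test_that("external DE tables import, validate and round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tlog2FC\tpvalue\tpadj",
               "g1\t2.5\t0.001\t0.01", "g2\t-0.2\t0.6\t0.8"), f)
  de <- importDETable(f)
  expect_equal(deTable(de)$log2_fold_change, c(2.5, -0.2))
  expect_equal(provenance(de)$source, "external")
  exportDETable(de, f)
  expect_equal(deTable(importDETable(f))$fdr, c(0.01, 0.8))
  writeLines(c("gene\tlog2FC\tpvalue", "g1\t1\t0.1"), f)
  expect_error(importDETable(f), "padj")
})

test_that("spermatogenesis-specific rules gate on RPKM, FDR and genotype overlap", {
  genes <- c("gIncl", "gOocyteHigh", "gOneGenotype", "gWeakFdr")
  ## columns: sp wild_type, sp him_8, oogenic wild_type
  r <- rbind(gIncl = c(20, 22, 0.5),
             gOocyteHigh = c(20, 22, 1.5),
             gOneGenotype = c(20, 22, 0.5),
             gWeakFdr = c(20, 22, 0.5))
  colnames(r) <- c("spWT", "spHim", "oo")
  expr <- rpkmFixture(r, c("spermatogenic", "spermatogenic", "oogenic"),
                      c("wild_type", "him_8", "wild_type"))
  de <- list(
    wild_type = deFixture(genes, lfc = c(4, 4, 4, 4),
                          fdr = c(0.01, 0.01, 0.01, 0.2)),
    him_8 = deFixture(genes, lfc = c(4, 4, 4, 4),
                      fdr = c(0.01, 0.01, 0.5, 0.01)))
  out <- buildSpermatogenesisSet(expr, de)
  expect_identical(geneIds(out$final), "gIncl")
  ## per-genotype intermediates keep the one-genotype pass
  expect_true("gOneGenotype" %in% geneIds(out$perGenotype$wild_type))
  expect_false("gOneGenotype" %in% geneIds(out$perGenotype$him_8))
  expect_error(buildSpermatogenesisSet(expr, de["wild_type"]), "two named")
})

test_that("sex-independent rules demand expression in both and a null FDR", {
  genes <- c("gIncl", "gSig", "gBigFc", "gLowRpkm")
  r <- rbind(gIncl = c(10, 10, 10),
             gSig = c(10, 10, 10),
             gBigFc = c(10, 10, 10),
             gLowRpkm = c(10, 10, 4))
  colnames(r) <- c("spWT", "spHim", "oo")
  expr <- rpkmFixture(r, c("spermatogenic", "spermatogenic", "oogenic"),
                      c("wild_type", "him_8", "wild_type"))
  de <- list(
    wild_type = deFixture(genes, lfc = c(0.1, 0.1, 2.5, 0.1),
                          fdr = c(0.5, 0.01, 0.5, 0.5)),
    him_8 = deFixture(genes, lfc = c(0.1, 0.1, 2.5, 0.1),
                      fdr = c(0.5, 0.01, 0.5, 0.5)))
  out <- buildSexIndependentSet(expr, de)
  expect_identical(geneIds(out$final), "gIncl")
})

test_that("spermatogenesis and sex-independent sets are disjoint by construction", {
  cfg <- simConfig(seed = 77, nAutosomes = 2, chromLength = 3e5,
                   nGenesPerChrom = 60)
  sim <- simulateGenome(cfg)
  expr <- computeRPKM(simulateExpression(sim$genes, sim$truth, cfg))
  cd <- SummarizedExperiment::colData(expr)
  oog <- rownames(cd)[cd$germline_type == "oogenic"]
  de <- lapply(c(wild_type = "wild_type", him_8 = "him_8"), function(g)
    nbTwoGroupTest(expr, oog,
                   rownames(cd)[cd$germline_type == "spermatogenic" &
                                  cd$genotype == g]))
  ss <- buildSpermatogenesisSet(expr, de)
  si <- buildSexIndependentSet(expr, de)
  expect_length(intersect(geneIds(ss$final), geneIds(si$final)), 0)
  expect_gt(length(ss$final), 0)
})

test_that("misregulation overlap sets follow the two-threshold FDR logic", {
  genes <- paste0("g", 1:6)
  parent <- deFixture(genes, lfc = c(2, 2, 0.1, 2, -2, 2),
                      fdr = c(0.01, 0.01, 0.9, 0.01, 0.01, 0.01))
  sperm <- deFixture(genes, lfc = c(2, 0.1, 2, 0.1, -2, 1),
                     fdr = c(0.01, 0.9, 0.01, 0.10, 0.01, 0.30))
  out <- buildDEOverlapSets(parent, sperm)
  ## g1: up in both; g2: up parent / null sperm; g3: up sperm / null parent
  expect_identical(geneIds(out$sets$up_parent_and_sperm), "g1")
  expect_identical(geneIds(out$sets$up_parent_not_sperm),
                   c("g2", "g6"))
  expect_identical(geneIds(out$sets$up_sperm_not_parent), "g3")
  ## g4: sperm FDR in (0.05, 0.2) is indeterminate -> in no set
  expect_false("g4" %in% unlist(lapply(out$sets, geneIds)))
  ## pairwise disjointness
  expect_length(intersect(geneIds(out$sets$up_parent_and_sperm),
                          geneIds(out$sets$up_parent_not_sperm)), 0)
  ## Venn counts: down-down overlap sees g5
  dn <- out$venn[out$venn$direction == "down", ]
  expect_equal(dn$overlap, 1)
})
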