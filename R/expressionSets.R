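## expression_sets: RPKM, a negative-binomial two-group Wald test with
## Benjamini-Hochberg adjustment (an authored simplification of the NB-GLM
## machinery the field's standard tool uses: median-of-ratios size factors,
## pooled method-of-moments dispersion shrunk toward a parametric 1/mu
## trend, Wald test on the log2 ratio of group means), and the explicit
## RPKM/FDR gene-set construction rules with genotype-intersection logic.

#' Gene-set rule thresholds
#'
#' The thresholds ARE the analysis: RPKM > 15 defines "expressed";
#' spermatogenesis-specific genes need spermatogenic RPKM > 15, wild-type
#' oogenic RPKM < 1 and FDR < 0.05 for spermatogenic-high expression;
#' sex-independent genes need both RPKMs > 5, FDR > 0.05 and
#' |log2 fold change| < 2; the two-threshold misregulation logic calls
#' FDR < 0.05 "changed" and FDR >= 0.2 "not changed".
#'
#' @param expressedRpkm,spermspecOocyteMaxRpkm,sexindepMinRpkm,sexindepMaxAbsLog2fc,fdrSig,fdrNull
#'   thresholds as above.
#' @param reduce how replicate RPKMs are reduced per condition before
#'   thresholding: `"mean"` (default), `"median"`, or `"all"` (every
#'   replicate must pass).
#' @return validated list of rules.
#' @export
setRuleConfig <- function(expressedRpkm = 15, spermspecOocyteMaxRpkm = 1,
                          sexindepMinRpkm = 5, sexindepMaxAbsLog2fc = 2,
                          fdrSig = 0.05, fdrNull = 0.2,
                          reduce = c("mean", "median", "all")) {
  stopifnot(expressedRpkm > 0, spermspecOocyteMaxRpkm > 0,
            sexindepMinRpkm > 0, sexindepMaxAbsLog2fc > 0,
            fdrSig > 0, fdrNull > 0, fdrSig < fdrNull)
  list(expressedRpkm = expressedRpkm,
       spermspecOocyteMaxRpkm = spermspecOocyteMaxRpkm,
       sexindepMinRpkm = sexindepMinRpkm,
       sexindepMaxAbsLog2fc = sexindepMaxAbsLog2fc,
       fdrSig = fdrSig, fdrNull = fdrNull, reduce = match.arg(reduce))
}

#' Compute RPKM
#'
#' `RPKM[g, s] = count[g, s] / (transcript_length_kb[g] x column_total[s] / 1e6)`
#' — counts per kilobase of exonic transcript per million mapped reads.
#'
#' @param expr an [ExpressionTable-class]. Transcript lengths are taken from
#'   `rowData(expr)$transcript_length` or from `lengths`.
#' @param lengths optional named vector of exonic transcript lengths (bp).
#' @return the [ExpressionTable-class] with an added `rpkm` assay.
#' @export
computeRPKM <- function(expr, lengths = NULL) {
  stopifnot(is(expr, "ExpressionTable"))
  cnt <- SummarizedExperiment::assay(expr, "counts")
  if (is.null(lengths))
    lengths <- stats::setNames(
      SummarizedExperiment::rowData(expr)$transcript_length, rownames(cnt))
  miss <- rownames(cnt)[!(rownames(cnt) %in% names(lengths)) |
                          is.na(lengths[rownames(cnt)])]
  if (length(miss))
    stop("missing transcript length for: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5))
  len <- lengths[rownames(cnt)]
  tot <- colSums(cnt)
  if (any(tot == 0))
    stop("zero column total in sample(s): ",
         paste(colnames(cnt)[tot == 0], collapse = ", "))
  rpkm <- sweep(cnt / (len / 1000), 2, tot / 1e6, "/")
  SummarizedExperiment::assay(expr, "rpkm", withDimnames = FALSE) <- rpkm
  expr
}

#' @rdname accessors
#' @export
setGeneric("rpkm", function(x) standardGeneric("rpkm"))

#' @rdname accessors
#' @export
setMethod("rpkm", "ExpressionTable", function(x) {
  if (!"rpkm" %in% SummarizedExperiment::assayNames(x))
    stop("run computeRPKM() first")
  SummarizedExperiment::assay(x, "rpkm")
})

## condition-mean RPKM: reduce replicate columns per the rule config
.reduceRpkm <- function(rpkmMat, cols, reduce) {
  sub <- rpkmMat[, cols, drop = FALSE]
  switch(reduce,
         mean = rowMeans(sub),
         median = apply(sub, 1, stats::median),
         all = sub)
}

#' Call expressed genes per condition
#'
#' Genes with condition-reduced RPKM strictly greater than the threshold
#' (default 15) are called expressed; conditions are
#' `germline_type x genotype` combinations present in the metadata.
#'
#' @param expr an [ExpressionTable-class] with an `rpkm` assay.
#' @param threshold RPKM cutoff (strict >; default 15).
#' @param reduce replicate reduction (`"mean"` default).
#' @return named list of [GeneList-class], one per condition.
#' @export
callExpressed <- function(expr, threshold = 15, reduce = "mean") {
  r <- rpkm(expr)
  cd <- SummarizedExperiment::colData(expr)
  cond <- paste(cd$germline_type, cd$genotype, sep = ".")
  out <- lapply(unique(cond), function(cc) {
    m <- .reduceRpkm(r, which(cond == cc), reduce)
    GeneList(rownames(r)[m > threshold], name = paste0("expressed.", cc),
             provenance = sprintf("RPKM > %g (%s over replicates)",
                                  threshold, reduce))
  })
  stats::setNames(out, unique(cond))
}

#' Negative-binomial two-group differential-expression test
#'
#' Per gene: median-of-ratios size factors; pooled within-group
#' method-of-moments NB dispersion, shrunk in log space toward a parametric
#' `a0 + a1/mu` mean-dispersion trend; Wald test on the log2 ratio of
#' normalized group means (delta-method standard error); BH adjustment over
#' tested genes. Genes with all-zero counts are excluded from testing
#' (`tested = FALSE`, NA statistics). Positive log2 fold change means group
#' B is higher.
#'
#' @param expr an [ExpressionTable-class] or counts matrix.
#' @param groupA,groupB column names (or indices) of the two groups; at
#'   least one sample each (single-replicate groups use a blind pooled
#'   dispersion with a warning; >= 2 per group is recommended).
#' @param priorDf weight of the trend in dispersion shrinkage (prior
#'   degrees of freedom; default 10).
#' @return A [DEResult-class].
#' @export
nbTwoGroupTest <- function(expr, groupA, groupB, priorDf = 10) {
  counts <- if (is(expr, "ExpressionTable"))
    SummarizedExperiment::assay(expr, "counts") else as.matrix(expr)
  if (is.character(groupA)) groupA <- match(groupA, colnames(counts))
  if (is.character(groupB)) groupB <- match(groupB, colnames(counts))
  if (anyNA(groupA) || anyNA(groupB)) stop("unknown sample in group definition")
  nA <- length(groupA); nB <- length(groupB)
  if (nA == 0 || nB == 0) stop("each group needs at least one sample")
  if (min(nA, nB) < 2)
    warning("single-replicate group: using blind pooled dispersion")
  use <- c(groupA, groupB)
  cnt <- counts[, use, drop = FALSE]
  tested <- rowSums(cnt) > 0
  sf <- .medianOfRatios(cnt)
  q <- sweep(cnt, 2, sf, "/")
  iA <- seq_len(nA); iB <- nA + seq_len(nB)
  qA <- rowMeans(q[, iA, drop = FALSE])
  qB <- rowMeans(q[, iB, drop = FALSE])
  baseMean <- rowMeans(q)
  xiA <- mean(1 / sf[iA]); xiB <- mean(1 / sf[iB])
  df <- nA + nB - 2
  if (min(nA, nB) >= 2) {
    ssq <- rowSums((q[, iA, drop = FALSE] - qA)^2) +
      rowSums((q[, iB, drop = FALSE] - qB)^2)
    v <- ssq / df
    poisTerm <- ((nA - 1) * qA * xiA + (nB - 1) * qB * xiB) / df
    sqTerm <- ((nA - 1) * qA^2 + (nB - 1) * qB^2) / df
  } else {
    ## blind: one pooled group
    df <- nA + nB - 1
    v <- apply(q, 1, stats::var)
    poisTerm <- baseMean * mean(1 / sf)
    sqTerm <- baseMean^2
  }
  dispRaw <- ifelse(sqTerm > 0, (v - poisTerm) / sqTerm, 0)
  dispTrend <- .dispersionTrend(dispRaw, baseMean, tested)
  w <- df / (df + priorDf)
  dispFloor <- pmax(dispRaw, dispTrend / 10, 1e-8)
  disp <- exp(w * log(dispFloor) + (1 - w) * log(dispTrend))
  disp <- pmin(disp, 20)
  ## Wald test on log2(qB / qA), half-count prior stabilizes zero means
  s0 <- 0.5 * mean(1 / sf)
  mA <- qA + s0; mB <- qB + s0
  lfc <- log2(mB / mA)
  varA <- (mA * xiA + disp * mA^2) / nA
  varB <- (mB * xiB + disp * mB^2) / nB
  se <- sqrt(varA / mA^2 + varB / mB^2) / log(2)
  z <- lfc / se
  p <- 2 * stats::pnorm(-abs(z))
  p[!tested] <- NA
  lfc[!tested] <- NA
  fdr <- rep(NA_real_, length(p))
  fdr[tested] <- benjaminiHochberg(p[tested])
  tab <- data.frame(gene = rownames(counts) %||% as.character(seq_len(nrow(counts))),
                    base_mean = baseMean, log2_fold_change = lfc,
                    p_value = p, fdr = fdr, tested = tested,
                    row.names = NULL)
  new("DEResult", table = tab,
      provenance = list(source = "internal",
                        group_a = colnames(counts)[groupA],
                        group_b = colnames(counts)[groupB],
                        orientation = "positive log2FC = group B higher",
                        size_factors = sf, prior_df = priorDf))
}

## median-of-ratios size factors (geometric-mean reference); falls back to
## relative library size if no gene is positive in all samples
.medianOfRatios <- function(cnt) {
  logGeo <- rowMeans(log(cnt))
  use <- is.finite(logGeo)
  if (!any(use)) {
    sf <- colSums(cnt)
    return(sf / exp(mean(log(sf))))
  }
  apply(cnt, 2, function(col) exp(stats::median(log(col[use]) - logGeo[use])))
}

## parametric dispersion-mean trend a0 + a1/mu, gamma-family fit as in the
## standard NB-GLM tooling; falls back to the median positive dispersion
.dispersionTrend <- function(dispRaw, baseMean, tested) {
  ok <- tested & baseMean > 1 & dispRaw > 1e-6
  fallback <- stats::median(dispRaw[tested & dispRaw > 0])
  if (!is.finite(fallback) || fallback <= 0) fallback <- 0.01
  if (sum(ok) < 10) return(rep(fallback, length(dispRaw)))
  fit <- tryCatch(
    stats::glm(dispRaw[ok] ~ I(1 / baseMean[ok]),
               family = stats::Gamma(link = "identity"),
               start = c(fallback, 1)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) return(rep(fallback, length(dispRaw)))
  a0 <- max(stats::coef(fit)[1], 1e-6)
  a1 <- max(stats::coef(fit)[2], 0)
  pmax(a0 + a1 / baseMean, 1e-6)
}

#' Import an externally produced differential-expression table
#'
#' Compatibility path for exact reproduction of published DE calls: a TSV
#' with columns `gene`, `log2FC`, `pvalue`, `padj`.
#'
#' @param path TSV file.
#' @return A [DEResult-class] with provenance `source = "external"`.
#' @export
importDETable <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("gene", "log2FC", "pvalue", "padj")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(gene = as.character(tab$gene),
                    base_mean = if ("baseMean" %in% colnames(tab))
                      tab$baseMean else NA_real_,
                    log2_fold_change = tab$log2FC, p_value = tab$pvalue,
                    fdr = tab$padj,
                    tested = !is.na(tab$pvalue))
  new("DEResult", table = out,
      provenance = list(source = "external", path = path))
}

#' Export a DEResult in import-compatible form
#' @param de a [DEResult-class].
#' @param path output TSV.
#' @export
exportDETable <- function(de, path) {
  tab <- deTable(de)
  out <- data.frame(gene = tab$gene, log2FC = tab$log2_fold_change,
                    pvalue = tab$p_value, padj = tab$fdr,
                    baseMean = tab$base_mean)
  writeTSV(out, path)
}

## helper: fdr/lfc lookups from a DEResult as named vectors
.deVec <- function(de) {
  tab <- deTable(de)
  list(fdr = stats::setNames(tab$fdr, tab$gene),
       lfc = stats::setNames(tab$log2_fold_change, tab$gene))
}

## condition-mean RPKM per (germline_type, genotype)
.conditionRpkm <- function(expr, germline, genotype, reduce) {
  cd <- SummarizedExperiment::colData(expr)
  cols <- which(cd$germline_type == germline & cd$genotype == genotype)
  if (!length(cols))
    stop(sprintf("no samples with germline_type '%s' and genotype '%s'",
                 germline, genotype))
  .reduceRpkm(rpkm(expr), cols, reduce)
}

#' Build the spermatogenesis-specific gene set
#'
#' Per male genotype: spermatogenic RPKM > 15, wild-type oogenic RPKM < 1,
#' FDR < 0.05 with spermatogenic-high orientation (positive log2FC given
#' the required oogenic-vs-spermatogenic comparison orientation). The final
#' set is the intersection of the per-genotype sets.
#'
#' @param expr an [ExpressionTable-class] with `rpkm` assay; metadata must
#'   contain spermatogenic samples for each genotype in `deByGenotype` and
#'   wild-type (`oogenicGenotype`) oogenic samples.
#' @param deByGenotype named list of [DEResult-class], one per male
#'   genotype, each from a comparison with group A = oogenic, group B =
#'   spermatogenic (positive log2FC = spermatogenic-high).
#' @param rules from [setRuleConfig()].
#' @param oogenicGenotype genotype of the oogenic reference samples.
#' @return list with `final` ([GeneList-class]) and `perGenotype` (named
#'   list of [GeneList-class]).
#' @export
buildSpermatogenesisSet <- function(expr, deByGenotype,
                                    rules = setRuleConfig(),
                                    oogenicGenotype = "wild_type") {
  if (length(deByGenotype) < 2 || is.null(names(deByGenotype)))
    stop("two named male-genotype comparisons are required")
  ooRpkm <- .conditionRpkm(expr, "oogenic", oogenicGenotype, rules$reduce)
  perGenotype <- lapply(names(deByGenotype), function(g) {
    spRpkm <- .conditionRpkm(expr, "spermatogenic", g, rules$reduce)
    de <- .deVec(deByGenotype[[g]])
    ids <- names(spRpkm)
    pass <- spRpkm > rules$expressedRpkm &
      ooRpkm[ids] < rules$spermspecOocyteMaxRpkm &
      !is.na(de$fdr[ids]) & de$fdr[ids] < rules$fdrSig &
      de$lfc[ids] > 0
    GeneList(ids[pass], name = paste0("spermatogenesis_specific.", g),
             provenance = sprintf(
               "sperm RPKM > %g & oogenic RPKM < %g & FDR < %g, genotype %s",
               rules$expressedRpkm, rules$spermspecOocyteMaxRpkm,
               rules$fdrSig, g))
  })
  names(perGenotype) <- names(deByGenotype)
  final <- Reduce(intersect, lapply(perGenotype, geneIds))
  list(final = GeneList(final, name = "spermatogenesis_specific",
                        provenance = paste("intersection of genotypes:",
                                           paste(names(deByGenotype),
                                                 collapse = " & "))),
       perGenotype = perGenotype)
}

#' Build the sex-independent gene set
#'
#' Per male genotype: spermatogenic RPKM > 5, oogenic RPKM > 5, FDR > 0.05
#' and |log2 fold change| < 2 (no significant differential expression);
#' final set = intersection across genotypes. Provably disjoint from the
#' spermatogenesis-specific set (oogenic RPKM < 1 vs > 5).
#'
#' @inheritParams buildSpermatogenesisSet
#' @return list with `final` and `perGenotype` as in
#'   [buildSpermatogenesisSet()].
#' @export
buildSexIndependentSet <- function(expr, deByGenotype,
                                   rules = setRuleConfig(),
                                   oogenicGenotype = "wild_type") {
  if (length(deByGenotype) < 2 || is.null(names(deByGenotype)))
    stop("two named male-genotype comparisons are required")
  ooRpkm <- .conditionRpkm(expr, "oogenic", oogenicGenotype, rules$reduce)
  perGenotype <- lapply(names(deByGenotype), function(g) {
    spRpkm <- .conditionRpkm(expr, "spermatogenic", g, rules$reduce)
    de <- .deVec(deByGenotype[[g]])
    ids <- names(spRpkm)
    pass <- spRpkm > rules$sexindepMinRpkm &
      ooRpkm[ids] > rules$sexindepMinRpkm &
      !is.na(de$fdr[ids]) & de$fdr[ids] > rules$fdrSig &
      abs(de$lfc[ids]) < rules$sexindepMaxAbsLog2fc
    GeneList(ids[pass], name = paste0("sex_independent.", g),
             provenance = sprintf(
               "both RPKM > %g & FDR > %g & |log2FC| < %g, genotype %s",
               rules$sexindepMinRpkm, rules$fdrSig,
               rules$sexindepMaxAbsLog2fc, g))
  })
  names(perGenotype) <- names(deByGenotype)
  final <- Reduce(intersect, lapply(perGenotype, geneIds))
  list(final = GeneList(final, name = "sex_independent",
                        provenance = paste("intersection of genotypes:",
                                           paste(names(deByGenotype),
                                                 collapse = " & "))),
       perGenotype = perGenotype)
}

#' Build the misregulation overlap sets of the inheritance experiment
#'
#' From parent-germline and sperm comparisons (mutant vs control), with the
#' two-threshold logic FDR < `fdrSig` = changed and FDR >= `fdrNull` = not
#' changed (in between is indeterminate and belongs to no set):
#' `up_parent_and_sperm`, `up_parent_not_sperm`, `up_sperm_not_parent`.
#' The universe is the genes tested in both comparisons. Also returns
#' up/down counts and all pairwise overlap counts across the supplied
#' comparisons (a Venn summary).
#'
#' @param deParent,deSperm [DEResult-class] for parent germlines and sperm
#'   (mutant vs control; positive log2FC = up in mutant).
#' @param deOffspring optional third comparison (offspring germlines)
#'   included in the Venn counts.
#' @param rules from [setRuleConfig()].
#' @return list: `sets` (three [GeneList-class]), `universe` (character),
#'   `venn` (data.frame of pairwise overlap counts).
#' @export
buildDEOverlapSets <- function(deParent, deSperm, deOffspring = NULL,
                               rules = setRuleConfig()) {
  comparisons <- list(parent = deParent, sperm = deSperm)
  if (!is.null(deOffspring)) comparisons$offspring <- deOffspring
  testedIds <- lapply(comparisons[c("parent", "sperm")], function(d) {
    tab <- deTable(d)
    tab$gene[tab$tested %||% TRUE & !is.na(tab$fdr)]
  })
  universe <- intersect(testedIds$parent, testedIds$sperm)
  if (!length(universe)) stop("gene universes do not intersect")
  stateOf <- function(de) {
    v <- .deVec(de)
    list(up = names(which(v$fdr < rules$fdrSig & v$lfc > 0)),
         down = names(which(v$fdr < rules$fdrSig & v$lfc < 0)),
         notchanged = names(which(v$fdr >= rules$fdrNull)))
  }
  st <- lapply(comparisons, stateOf)
  inU <- function(x) intersect(x, universe)
  set1 <- inU(intersect(st$parent$up, st$sperm$up))
  set2 <- inU(intersect(st$parent$up, st$sperm$notchanged))
  set3 <- inU(intersect(st$sperm$up, st$parent$notchanged))
  sets <- list(
    up_parent_and_sperm = GeneList(set1, "up_parent_and_sperm",
                                   "FDR<sig up in parent and in sperm"),
    up_parent_not_sperm = GeneList(set2, "up_parent_not_sperm",
                                   "up in parent, FDR>=null in sperm"),
    up_sperm_not_parent = GeneList(set3, "up_sperm_not_parent",
                                   "up in sperm, FDR>=null in parent"))
  ## pairwise Venn counts over up/down calls
  pairs <- utils::combn(names(comparisons), 2, simplify = FALSE)
  venn <- do.call(rbind, lapply(pairs, function(pr) {
    do.call(rbind, lapply(c("up", "down"), function(dir) {
      a <- st[[pr[1]]][[dir]]; b <- st[[pr[2]]][[dir]]
      data.frame(comparison_a = pr[1], comparison_b = pr[2], direction = dir,
                 n_a = length(a), n_b = length(b),
                 overlap = length(intersect(a, b)))
    }))
  }))
  list(sets = sets, universe = universe, venn = venn)
}
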