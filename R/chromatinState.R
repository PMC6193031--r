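## chromatin_state: log2(+1) transform, autosome-referenced z-scoring with a
## per-mark baseline (mean, or a percentile for the broad repressive mark
## H3K27me3, which covers too much of the genome for the autosomal mean to
## be a sensible zero), and the quadrant / multivalency classification.

#' Normalization configuration
#'
#' @param pseudoCount added before log2 (default 1).
#' @param baselines named list mark -> baseline spec, each either
#'   `list(type = "mean")` or `list(type = "percentile", p = <0-100>)`.
#'   Marks not listed use the mean. The default gives H3K27me3 a
#'   30th-percentile baseline and all other marks the autosomal mean.
#' @param quantileType quantile method for percentile baselines (default 7,
#'   linear interpolation between order statistics).
#' @return list used by [logTransform()] and [zscoreAgainstAutosomes()].
#' @export
transformConfig <- function(pseudoCount = 1,
                            baselines = list(
                              H3K27me3 = list(type = "percentile", p = 30)),
                            quantileType = 7) {
  stopifnot(pseudoCount > 0)
  for (b in baselines) {
    stopifnot(b$type %in% c("mean", "percentile"))
    if (b$type == "percentile") stopifnot(b$p > 0, b$p < 100)
  }
  list(pseudoCount = pseudoCount, baselines = baselines,
       quantileType = quantileType)
}

#' Log-transform raw mean coverages
#'
#' `v -> log2(v + pseudoCount)`.
#'
#' @param table a [MarkSignalTable-class] at stage `"raw_mean"`.
#' @param config from [transformConfig()].
#' @return A [MarkSignalTable-class] at stage `"log2p1"`.
#' @export
logTransform <- function(table, config = transformConfig()) {
  stopifnot(is(table, "MarkSignalTable"))
  if (signalStage(table) != "raw_mean")
    stop("logTransform requires stage 'raw_mean'")
  m <- signalMatrix(table)
  if (any(m < 0)) stop("negative input signal")
  out <- log2(m + config$pseudoCount)
  new("MarkSignalTable", signal = out, stage = "log2p1",
      windowMode = table@windowMode, isAutosomal = table@isAutosomal,
      provenance = c(provenance(table),
                     list(pseudo_count = config$pseudoCount)))
}

#' Z-score signal against autosomal genes
#'
#' For every gene (autosomal and X):
#' `z = (v - baseline(autosomal values)) / sd(autosomal values)`, where the
#' baseline is the autosomal mean, or for marks configured with a percentile
#' baseline (H3K27me3 by default, 30th percentile) that percentile of the
#' autosomal values. The scale is always the sample (n-1) standard deviation
#' of the autosomal values, regardless of baseline choice.
#'
#' @param table a [MarkSignalTable-class] at stage `"log2p1"`.
#' @param config from [transformConfig()].
#' @return A [MarkSignalTable-class] at stage `"zscore"`; the baselines and
#'   sds used are recorded in its provenance.
#' @export
zscoreAgainstAutosomes <- function(table, config = transformConfig()) {
  stopifnot(is(table, "MarkSignalTable"))
  if (signalStage(table) != "log2p1")
    stop("zscoreAgainstAutosomes requires stage 'log2p1'")
  auto <- table@isAutosomal
  if (sum(auto) < 2) stop("need >= 2 autosomal genes")
  m <- signalMatrix(table)
  out <- m
  used <- list()
  for (j in seq_len(ncol(m))) {
    mark <- colnames(m)[j]
    av <- m[auto, j]
    s <- stats::sd(av)
    if (s == 0) stop("zero autosomal standard deviation for ", mark)
    bspec <- config$baselines[[mark]] %||% list(type = "mean")
    b <- if (bspec$type == "percentile")
      unname(stats::quantile(av, bspec$p / 100, type = config$quantileType))
    else mean(av)
    out[, j] <- (m[, j] - b) / s
    used[[mark]] <- list(baseline_type = bspec$type,
                         baseline_p = bspec$p %||% NA,
                         baseline = b, sd = s)
  }
  new("MarkSignalTable", signal = out, stage = "zscore",
      windowMode = table@windowMode, isAutosomal = table@isAutosomal,
      provenance = c(provenance(table),
                     list(reference = used,
                          quantile_type = config$quantileType)))
}

#' Classify genes into mark quadrants
#'
#' For an (active mark, repressive mark) z-score pair, genes are labelled
#' `active_only` (z_a > t, z_r <= t), `repressive_only` (z_a <= t,
#' z_r > t), `both` (both > t) or `neither`. Ties at the threshold count as
#' unmarked (strict > for marked). The multivalency flag is `both`,
#' optionally additionally requiring H3K4me3 z above threshold.
#'
#' @param zActive,zRepressive single-mark [MarkSignalTable-class] objects at
#'   stage `"zscore"` over the same gene universe.
#' @param threshold quadrant boundary on the z scale (default 0, the
#'   centered axes of the scatter).
#' @param zK4 optional H3K4me3 z-score table; with `requireK4 = TRUE` the
#'   multivalency flag also requires `zK4 > threshold`.
#' @param requireK4 logical.
#' @return A [QuadrantCall-class].
#' @export
classifyQuadrants <- function(zActive, zRepressive, threshold = 0,
                              zK4 = NULL, requireK4 = FALSE) {
  for (t in list(zActive, zRepressive)) {
    stopifnot(is(t, "MarkSignalTable"))
    if (signalStage(t) != "zscore") stop("inputs must be at stage 'zscore'")
  }
  ga <- geneIds(zActive)
  if (!identical(ga, geneIds(zRepressive)))
    stop("gene universes of the two tables differ")
  za <- signalMatrix(zActive)[, 1]
  zr <- signalMatrix(zRepressive)[, 1]
  a <- za > threshold
  r <- zr > threshold
  label <- ifelse(a & r, "both",
                  ifelse(a, "active_only",
                         ifelse(r, "repressive_only", "neither")))
  multi <- a & r
  if (requireK4) {
    if (is.null(zK4)) stop("requireK4 = TRUE needs zK4")
    if (!identical(geneIds(zK4), ga)) stop("zK4 gene universe differs")
    multi <- multi & (signalMatrix(zK4)[, 1] > threshold)
  }
  new("QuadrantCall", gene = ga,
      label = factor(label, levels = QUADRANT_LEVELS),
      multivalent = unname(multi),
      params = list(threshold = threshold,
                    active_mark = colnames(signalMatrix(zActive))[1],
                    repressive_mark = colnames(signalMatrix(zRepressive))[1],
                    require_k4 = requireK4))
}

#' Per-gene-set quadrant percentages
#'
#' For each named gene set, the percentage of its (in-universe) genes in
#' each quadrant, plus an `either_exclusive` aggregate
#' (`active_only + repressive_only`, the "marked with either mark" reading).
#' Out-of-universe ids are dropped with a warning and reported in the
#' `n_dropped` column.
#'
#' @param calls a [QuadrantCall-class].
#' @param geneSets named list of [GeneList-class] objects (or id vectors).
#' @return data.frame, one row per set: `set`, `n_used`, `n_dropped`,
#'   the four quadrant percentages, and `either_exclusive`.
#' @export
summarizeClassMarking <- function(calls, geneSets) {
  stopifnot(is(calls, "QuadrantCall"))
  lab <- quadrantLabels(calls)
  rows <- lapply(names(geneSets), function(nm) {
    ids <- geneSets[[nm]]
    if (is(ids, "GeneList")) ids <- geneIds(ids)
    inUni <- ids %in% names(lab)
    if (any(!inUni))
      warning(sprintf("set '%s': %d id(s) outside the gene universe dropped",
                      nm, sum(!inUni)))
    ids <- ids[inUni]
    if (!length(ids))
      stop(sprintf("set '%s' is empty after intersection with the universe", nm))
    tab <- table(lab[ids])
    pct <- 100 * as.numeric(tab[QUADRANT_LEVELS]) / length(ids)
    pct[is.na(pct)] <- 0
    data.frame(set = nm, n_used = length(ids), n_dropped = sum(!inUni),
               active_only = pct[1], repressive_only = pct[2],
               both = pct[3], neither = pct[4],
               either_exclusive = pct[1] + pct[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
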