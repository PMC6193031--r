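#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames strand
#' @importFrom IRanges IRanges
NULL

## Default chromosome names treated as sex (X) chromosomes. The X is excluded
## from all scaling and reference (baseline/sd) statistics because the X:A
## ratio differs between sperm (X0), oocytes and embryos (XX).
DEFAULT_SEX_CHROMS <- c("X", "chrX")

#' CoverageTrack: stepwise per-base coverage signal
#'
#' A canonicalized bedGraph-like signal: per-chromosome sorted, non-overlapping
#' intervals with a non-negative value, stored as a `GRanges` with a `score`
#' column. Book-ended intervals with equal value are merged on construction so
#' that equal signals have equal representations. The track carries its
#' scaling state (`"raw"` or `"autosome-scaled"`) and the set of chromosome
#' names treated as the sex chromosome.
#'
#' @slot ranges `GRanges` with numeric `score`, sorted, non-overlapping.
#' @slot scaleState `"raw"` or `"autosome-scaled"`.
#' @slot sexChroms character vector of chromosome names excluded from
#'   autosomal totals (default `c("X", "chrX")`).
#'
#' @seealso [readBedGraph()], [scaleToAutosomalTarget()], [autosomalTotal()]
#' @export
setClass("CoverageTrack",
  representation(
    ranges = "GRanges",
    scaleState = "character",
    sexChroms = "character"
  )
)

setValidity("CoverageTrack", function(object) {
  gr <- object@ranges
  msg <- character(0)
  if (!"score" %in% colnames(S4Vectors::mcols(gr)))
    msg <- c(msg, "ranges must carry a 'score' metadata column")
  else {
    sc <- gr$score
    if (!is.numeric(sc) || anyNA(sc)) msg <- c(msg, "scores must be numeric and non-missing")
    else if (any(sc < 0)) msg <- c(msg, "scores must be >= 0")
  }
  if (!object@scaleState %in% c("raw", "autosome-scaled"))
    msg <- c(msg, "scaleState must be 'raw' or 'autosome-scaled'")
  if (length(gr) > 1L) {
    sp <- split(IRanges::ranges(gr), as.factor(seqnames(gr)))
    for (nm in names(sp)) {
      r <- sp[[nm]]
      if (length(r) > 1L) {
        if (is.unsorted(BiocGenerics::start(r)))
          msg <- c(msg, sprintf("intervals on %s are not sorted", nm))
        if (any(BiocGenerics::start(r)[-1L] <= BiocGenerics::end(r)[-length(r)]))
          msg <- c(msg, sprintf("overlapping intervals on %s", nm))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CoverageTrack
#'
#' Sorts intervals, merges book-ended runs of equal value, and validates
#' non-overlap and non-negativity.
#'
#' @param ranges `GRanges` with a numeric `score` column (1-based, closed, as
#'   usual for `GRanges`; the readers convert from 0-based half-open BED
#'   coordinates).
#' @param scaleState `"raw"` (default) or `"autosome-scaled"`.
#' @param sexChroms chromosome names classified as sex chromosomes.
#' @return A [CoverageTrack-class] object.
#' @export
CoverageTrack <- function(ranges, scaleState = "raw",
                          sexChroms = DEFAULT_SEX_CHROMS) {
  ranges <- GenomicRanges::sort(ranges)
  ranges <- .mergeBookended(ranges)
  new("CoverageTrack", ranges = ranges, scaleState = scaleState,
      sexChroms = sexChroms)
}

## merge adjacent intervals with identical value (canonical form)
.mergeBookended <- function(gr) {
  if (length(gr) < 2L) return(gr)
  sameChrom <- as.character(seqnames(gr))[-1L] == as.character(seqnames(gr))[-length(gr)]
  adjacent <- BiocGenerics::start(gr)[-1L] == BiocGenerics::end(gr)[-length(gr)] + 1L
  sameVal <- gr$score[-1L] == gr$score[-length(gr)]
  joins <- sameChrom & adjacent & sameVal
  if (!any(joins)) return(gr)
  grp <- cumsum(c(TRUE, !joins))
  starts <- tapply(BiocGenerics::start(gr), grp, min)
  ends <- tapply(BiocGenerics::end(gr), grp, max)
  first <- !duplicated(grp)
  out <- GRanges(seqnames(gr)[first], IRanges(as.integer(starts), as.integer(ends)),
                 score = gr$score[first], seqinfo = GenomeInfoDb::seqinfo(gr))
  out
}

setMethod("show", "CoverageTrack", function(object) {
  cat(sprintf("CoverageTrack: %d intervals on %d chromosome(s) [%s]\n",
              length(object@ranges),
              length(unique(as.character(seqnames(object@ranges)))),
              object@scaleState))
  cat(sprintf("  autosomal total: %.6g\n", autosomalTotal(object)))
})

#' MarkSignalTable: genes x marks signal values
#'
#' Holds per-gene signal for one or more histone marks at one of three
#' stages: `"raw_mean"` (mean per-base coverage over the quantification
#' window), `"log2p1"` (log2 after pseudo-count), or `"zscore"`
#' (autosome-referenced z-score). The table records the quantification window
#' mode per mark and the normalization provenance (baselines, scale, methods)
#' as it advances through the stages.
#'
#' @slot signal numeric matrix, rows = genes (rownames are gene ids),
#'   columns = marks.
#' @slot stage one of `"raw_mean"`, `"log2p1"`, `"zscore"`.
#' @slot windowMode character, one per column: `"gene_body"` or
#'   `"promoter"`.
#' @slot isAutosomal logical per gene; drives reference statistics.
#' @slot provenance list recording normalization parameters applied.
#' @export
setClass("MarkSignalTable",
  representation(
    signal = "matrix",
    stage = "character",
    windowMode = "character",
    isAutosomal = "logical",
    provenance = "list"
  )
)

setValidity("MarkSignalTable", function(object) {
  msg <- character(0)
  if (is.null(rownames(object@signal))) msg <- c(msg, "signal must have gene-id rownames")
  else if (anyDuplicated(rownames(object@signal))) msg <- c(msg, "duplicate gene ids")
  if (!object@stage %in% c("raw_mean", "log2p1", "zscore"))
    msg <- c(msg, "stage must be raw_mean, log2p1 or zscore")
  if (length(object@windowMode) != ncol(object@signal))
    msg <- c(msg, "one windowMode per mark column required")
  if (length(object@isAutosomal) != nrow(object@signal))
    msg <- c(msg, "isAutosomal must have one entry per gene")
  if (length(msg)) msg else TRUE
})

#' @param signal,stage,windowMode,isAutosomal,provenance see slots.
#' @rdname MarkSignalTable-class
#' @export
MarkSignalTable <- function(signal, stage, windowMode, isAutosomal,
                            provenance = list()) {
  if (is.null(dim(signal))) signal <- cbind(mark = signal)
  new("MarkSignalTable", signal = signal, stage = stage,
      windowMode = rep(windowMode, length.out = ncol(signal)),
      isAutosomal = isAutosomal, provenance = provenance)
}

setMethod("show", "MarkSignalTable", function(object) {
  cat(sprintf("MarkSignalTable: %d genes x %d mark(s) [%s]\n",
              nrow(object@signal), ncol(object@signal), object@stage))
  cat("  marks:", paste(colnames(object@signal), collapse = ", "), "\n")
})

#' ExpressionTable: genes x samples counts with metadata
#'
#' A `SummarizedExperiment` holding a `counts` assay (non-negative integers),
#' per-sample metadata (`germline_type`, `genotype`, `replicate`) in
#' `colData`, and per-gene annotation (`transcript_length`, chromosome class)
#' in `rowData`. [computeRPKM()] adds an `rpkm` assay.
#'
#' @export
setClass("ExpressionTable", contains = "SummarizedExperiment")

setValidity("ExpressionTable", function(object) {
  msg <- character(0)
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "a 'counts' assay is required")
  else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(cnt != round(cnt))) msg <- c(msg, "counts must be integers")
  }
  need <- c("germline_type", "genotype", "replicate")
  miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    msg <- c(msg, paste("missing sample metadata:", paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' @param counts genes x samples matrix of non-negative integers.
#' @param sampleInfo data.frame with `germline_type`, `genotype`, `replicate`.
#' @param geneInfo optional data.frame of per-gene annotation
#'   (e.g. `transcript_length`, `is_autosomal`), rownames = gene ids.
#' @rdname ExpressionTable-class
#' @export
ExpressionTable <- function(counts, sampleInfo, geneInfo = NULL) {
  counts <- as.matrix(counts)
  if (is.null(geneInfo)) geneInfo <- DataFrame(row.names = rownames(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(sampleInfo, row.names = colnames(counts)),
    rowData = geneInfo
  )
  new("ExpressionTable", se)
}

#' DEResult: per-gene differential-expression results
#'
#' @slot table data.frame with columns `gene`, `base_mean`,
#'   `log2_fold_change`, `p_value`, `fdr` (Benjamini-Hochberg adjusted), and
#'   `tested` (FALSE for all-zero genes, which are excluded from testing).
#' @slot provenance list: group definitions, orientation
#'   (positive log2FC = group B higher), and whether the result was computed
#'   internally or imported.
#' @export
setClass("DEResult",
  representation(table = "data.frame", provenance = "list"))

setValidity("DEResult", function(object) {
  need <- c("gene", "log2_fold_change", "p_value", "fdr")
  miss <- setdiff(need, colnames(object@table))
  if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
  fdr <- object@table$fdr
  ok <- is.na(fdr) | (fdr >= 0 & fdr <= 1)
  if (!all(ok)) return("fdr values must lie in [0, 1]")
  if (anyDuplicated(object@table$gene)) return("duplicate gene ids")
  TRUE
})

setMethod("show", "DEResult", function(object) {
  tab <- object@table
  nsig <- sum(tab$fdr < 0.05, na.rm = TRUE)
  cat(sprintf("DEResult: %d genes (%d tested), %d at FDR < 0.05 [%s]\n",
              nrow(tab), sum(tab$tested %||% TRUE), nsig,
              object@provenance$source %||% "internal"))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' GeneList: a named set of gene ids with provenance
#'
#' @slot ids unique character gene ids.
#' @slot name short label for the set.
#' @slot provenance free-text origin (rule, publication tag, file).
#' @export
setClass("GeneList",
  representation(ids = "character", name = "character", provenance = "character"))

setValidity("GeneList", function(object) {
  if (anyDuplicated(object@ids)) "gene ids must be unique" else TRUE
})

#' @param ids,name,provenance see slots.
#' @rdname GeneList-class
#' @export
GeneList <- function(ids, name = "gene_set", provenance = "unspecified") {
  new("GeneList", ids = as.character(ids), name = name, provenance = provenance)
}

setMethod("show", "GeneList", function(object) {
  cat(sprintf("GeneList '%s': %d genes (%s)\n",
              object@name, length(object@ids), object@provenance))
})

#' @export
setMethod("length", "GeneList", function(x) length(x@ids))

#' QuadrantCall: per-gene chromatin-state quadrant labels
#'
#' Partition of a gene universe into `active_only`, `repressive_only`,
#' `both` and `neither` for an (active mark, H3K27me3) pair, plus a
#' multivalency flag (gene called `both`, optionally also requiring
#' H3K4me3 above threshold).
#'
#' @slot gene gene ids.
#' @slot label factor over the four quadrants.
#' @slot multivalent logical.
#' @slot params list: marks used, threshold.
#' @export
setClass("QuadrantCall",
  representation(gene = "character", label = "factor",
                 multivalent = "logical", params = "list"))

QUADRANT_LEVELS <- c("active_only", "repressive_only", "both", "neither")

setValidity("QuadrantCall", function(object) {
  msg <- character(0)
  if (length(object@gene) != length(object@label) ||
      length(object@gene) != length(object@multivalent))
    msg <- c(msg, "gene, label and multivalent must have equal length")
  if (!identical(levels(object@label), QUADRANT_LEVELS))
    msg <- c(msg, "label levels must be the four quadrants")
  if (length(msg)) msg else TRUE
})

setMethod("show", "QuadrantCall", function(object) {
  cat(sprintf("QuadrantCall: %d genes\n", length(object@gene)))
  pct <- 100 * table(object@label) / length(object@label)
  for (nm in names(pct)) cat(sprintf("  %-16s %5.1f%%\n", nm, pct[[nm]]))
  cat(sprintf("  multivalent      %d genes\n", sum(object@multivalent)))
})

#' WindowOccupancyTable: tiled-window fragment coverage across samples
#'
#' @slot windows `GRanges` of fixed-width windows tiling each chromosome at
#'   the configured step (only fully in-bounds windows).
#' @slot coverage windows x samples matrix of mean per-base scaled fragment
#'   depth.
#' @slot rawCounts windows x samples matrix of unscaled fragment overlap
#'   counts (basis of the default exclusion rule).
#' @slot excluded logical per window (set by [excludeLowCoverage()]).
#' @slot params list: window length, step, scaling target, exclusion mode.
#' @export
setClass("WindowOccupancyTable",
  representation(windows = "GRanges", coverage = "matrix",
                 rawCounts = "matrix", excluded = "logical", params = "list"))

setValidity("WindowOccupancyTable", function(object) {
  msg <- character(0)
  if (nrow(object@coverage) != length(object@windows))
    msg <- c(msg, "coverage rows must match windows")
  if (!identical(dim(object@coverage), dim(object@rawCounts)))
    msg <- c(msg, "coverage and rawCounts must have identical dimensions")
  if (length(object@excluded) &&
      length(object@excluded) != length(object@windows))
    msg <- c(msg, "excluded must have one flag per window")
  if (length(msg)) msg else TRUE
})

setMethod("show", "WindowOccupancyTable", function(object) {
  cat(sprintf("WindowOccupancyTable: %d windows (%d bp / step %d bp) x %d sample(s)\n",
              length(object@windows), object@params$window_length %||% NA,
              object@params$step %||% NA, ncol(object@coverage)))
  if (length(object@excluded))
    cat(sprintf("  excluded: %d windows (%.2f%%)\n", sum(object@excluded),
                100 * mean(object@excluded)))
})
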