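## coverage_signal: autosome-referenced track scaling, per-gene body and
## promoter signal quantification, and metagene TSS/TES profiles. All means
## are computed over the full window with uncovered bases counting as zero
## ("mean0" semantics): sparse genes are not inflated and the z-score
## baseline downstream stays interpretable.

#' Scale a track to a target total autosomal signal
#'
#' Multiplies every value (autosomal and X alike) by
#' `target / autosomalTotal(track)`. The X is excluded from the reference
#' total because the X:A ratio differs between sperm, oocytes and embryos,
#' but X values are rescaled by the same factor so cross-chromosome
#' comparisons stay meaningful.
#'
#' @param track a raw [CoverageTrack-class].
#' @param target total autosomal signal after scaling (default 1e7,
#'   i.e. 10 million autosomal reads-equivalent).
#' @return An autosome-scaled [CoverageTrack-class].
#' @export
scaleToAutosomalTarget <- function(track, target = 1e7) {
  stopifnot(is(track, "CoverageTrack"))
  if (scaleState(track) != "raw")
    stop("track is already scaled")
  if (target <= 0) stop("target must be > 0")
  tot <- autosomalTotal(track)
  if (tot <= 0) stop("cannot scale: track has no autosomal signal")
  gr <- trackRanges(track)
  gr$score <- gr$score * (target / tot)
  CoverageTrack(gr, scaleState = "autosome-scaled",
                sexChroms = sexChroms(track))
}

#' Mean per-base signal per gene
#'
#' For `window = "gene_body"`, the window is the annotated gene span. For
#' `window = "promoter"`, it is `flank` bp either side of the gene start
#' annotation; by default the start is interpreted strand-aware (the TSS,
#' i.e. the higher coordinate for minus-strand genes), with
#' `strandAware = FALSE` available for the strand-naive reading. Windows are
#' clipped at chromosome bounds where lengths are known; uncovered bases
#' count as zero. Genes on chromosomes absent from the track get 0 with one
#' warning.
#'
#' @param track a scaled [CoverageTrack-class].
#' @param genes `GRanges` from [readGeneAnnotation()] or [simulateGenome()].
#' @param window `"gene_body"` or `"promoter"`.
#' @param flank promoter half-width in bp (default 500).
#' @param mark column name for the resulting table (default "signal").
#' @param strandAware promoter anchored at the strand-aware TSS (default)
#'   or at the lower coordinate regardless of strand.
#' @return A [MarkSignalTable-class] at stage `"raw_mean"`.
#' @export
geneMeanCoverage <- function(track, genes, window = c("gene_body", "promoter"),
                             flank = 500, mark = "signal",
                             strandAware = TRUE) {
  stopifnot(is(track, "CoverageTrack"))
  window <- match.arg(window)
  if (scaleState(track) != "autosome-scaled")
    warning("quantifying an unscaled track")
  chromLens <- .chromLens(genes)
  chrom <- as.character(seqnames(genes))
  if (window == "gene_body") {
    start0 <- BiocGenerics::start(genes) - 1
    end0 <- BiocGenerics::end(genes)
  } else {
    minus <- as.character(strand(genes)) == "-"
    anchor0 <- BiocGenerics::start(genes) - 1
    if (strandAware)
      anchor0[minus] <- BiocGenerics::end(genes)[minus]
    start0 <- anchor0 - flank
    end0 <- anchor0 + flank
  }
  win <- .clippedWindows(chrom, start0, end0, chromLens)
  rle <- .trackRle(track)
  absent <- !(chrom %in% names(rle))
  if (any(absent))
    warning(sprintf("%d gene(s) on chromosome(s) absent from track; signal 0",
                    sum(absent)))
  vals <- .windowMeans(rle, win)
  vals[is.na(vals)] <- 0
  m <- matrix(vals, ncol = 1, dimnames = list(genes$gene_id, mark))
  MarkSignalTable(m, stage = "raw_mean",
                  windowMode = if (window == "promoter")
                    sprintf("promoter±%d", flank) else "gene_body",
                  isAutosomal = genes$is_autosomal,
                  provenance = list(scale_state = scaleState(track),
                                    window = window, flank = flank,
                                    strand_aware = strandAware))
}

#' Metagene profile around TSS or TES
#'
#' Per-gene signal in fixed-width bins tiling `[-flank, +flank)` around the
#' strand-oriented anchor (bins run upstream to downstream in the gene's
#' direction), averaged over genes. Bins extending past chromosome ends
#' contribute only their in-bounds bases; genes whose bin is entirely out of
#' bounds do not contribute to that bin.
#'
#' @param track a scaled [CoverageTrack-class].
#' @param genes `GRanges` gene subset (non-empty).
#' @param anchor `"TSS"` or `"TES"`.
#' @param flank half-width in bp (default 1000).
#' @param binWidth bin width in bp (default 50); must divide `2*flank`.
#' @return data.frame with `bin_start`, `bin_end` (bp relative to anchor,
#'   upstream negative), `mean_signal`, `n_genes`.
#' @export
metageneProfile <- function(track, genes, anchor = c("TSS", "TES"),
                            flank = 1000, binWidth = 50) {
  stopifnot(is(track, "CoverageTrack"))
  anchor <- match.arg(anchor)
  if (length(genes) == 0) stop("empty gene set")
  if ((2 * flank) %% binWidth != 0)
    stop("binWidth must divide 2*flank")
  nBins <- as.integer(2 * flank / binWidth)
  minus <- as.character(strand(genes)) == "-"
  ## 0-based anchor coordinate of the strand-aware TSS/TES
  anchor0 <- if (anchor == "TSS")
    ifelse(minus, BiocGenerics::end(genes), BiocGenerics::start(genes) - 1)
  else
    ifelse(minus, BiocGenerics::start(genes) - 1, BiocGenerics::end(genes))
  rel <- seq(-flank, flank - binWidth, by = binWidth)
  chromLens <- .chromLens(genes)
  rle <- .trackRle(track)
  chrom <- as.character(seqnames(genes))
  acc <- matrix(0, length(genes), nBins)
  for (b in seq_len(nBins)) {
    s0 <- ifelse(minus, anchor0 - rel[b] - binWidth, anchor0 + rel[b])
    e0 <- s0 + binWidth
    win <- .clippedWindows(chrom, s0, e0, chromLens)
    acc[, b] <- .windowMeans(rle, win)
  }
  data.frame(bin_start = rel, bin_end = rel + binWidth,
             mean_signal = colMeans(acc, na.rm = TRUE),
             n_genes = colSums(!is.na(acc)))
}
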