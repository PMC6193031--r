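## Internal helpers shared across modules.

## Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
## All stochastic operations in the package funnel through this so that a
## SimConfig seed fixes outputs bit-for-bit without clobbering the session RNG.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  eval.parent(substitute(expr))
}

## Derive a reproducible sub-seed < 2^31 from a base seed and a task offset.
.subSeed <- function(seed, offset) {
  (as.numeric(seed) * 7919 + as.numeric(offset)) %% 2147483629
}

## Per-base Rle coverage of a CoverageTrack, one Rle per chromosome.
.trackRle <- function(track) {
  gr <- trackRanges(track)
  GenomicRanges::coverage(gr, weight = gr$score)
}

## Mean per-base signal over 1-based closed windows, counting bases beyond
## the Rle extent (i.e. with no recorded signal) as zero. `windows` must
## already be clipped to chromosome bounds where bounds are known; widths of
## zero yield NA.
.windowMeans <- function(rleList, windows) {
  n <- length(windows)
  out <- numeric(n)
  chrom <- as.character(seqnames(windows))
  st <- BiocGenerics::start(windows)
  en <- BiocGenerics::end(windows)
  for (nm in unique(chrom)) {
    idx <- which(chrom == nm)
    rle <- if (nm %in% names(rleList)) rleList[[nm]] else S4Vectors::Rle(numeric(0))
    maxEnd <- max(en[idx])
    if (length(rle) < maxEnd)
      rle <- c(rle, S4Vectors::Rle(0, maxEnd - length(rle)))
    v <- IRanges::Views(rle, start = st[idx], end = en[idx])
    out[idx] <- IRanges::viewMeans(v)
  }
  out[en < st] <- NA_real_
  out
}

## Sum (rather than mean) variant, used by brute-force-style totals.
.windowSums <- function(rleList, windows) {
  n <- length(windows)
  out <- numeric(n)
  chrom <- as.character(seqnames(windows))
  st <- BiocGenerics::start(windows)
  en <- BiocGenerics::end(windows)
  for (nm in unique(chrom)) {
    idx <- which(chrom == nm)
    rle <- if (nm %in% names(rleList)) rleList[[nm]] else S4Vectors::Rle(numeric(0))
    maxEnd <- max(en[idx])
    if (length(rle) < maxEnd)
      rle <- c(rle, S4Vectors::Rle(0, maxEnd - length(rle)))
    v <- IRanges::Views(rle, start = st[idx], end = en[idx])
    out[idx] <- IRanges::viewSums(v)
  }
  out
}

## Clip 0-based half-open [s, e) windows to [0, chromLen) and return a
## 1-based closed GRanges. chromLens may be NA (unknown length: clip at 0 only).
.clippedWindows <- function(chrom, start0, end0, chromLens = NULL) {
  s <- pmax(start0, 0)
  e <- end0
  if (!is.null(chromLens)) {
    len <- chromLens[chrom]
    known <- !is.na(len)
    e[known] <- pmin(e[known], len[known])
  }
  e <- pmax(e, s)  # empty windows allowed; callers decide how to treat them
  GRanges(chrom, IRanges(s + 1, e))
}

## Extract seqlengths (may be NA) as a plain named numeric vector.
.chromLens <- function(gr) {
  sl <- GenomeInfoDb::seqlengths(gr)
  stats::setNames(as.numeric(sl), names(sl))
}
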