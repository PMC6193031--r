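## mnase_occupancy: nucleosomal fragment filtering, autosome-scaled
## tiled-window coverage at multiple scales, low-coverage (low-mappability)
## window exclusion across samples, and autosome-vs-X occupancy summaries.

#' MNase analysis configuration
#'
#' @param minFragmentLength fragments shorter than this are discarded
#'   (default 140 bp, keeping nucleosome-protected fragments; "length >=
#'   140" is kept).
#' @param windowGrid list of `c(window_length, step)` pairs; defaults
#'   (150,50), (500,250), (1000,500), (2000,1000), (5000,2500).
#' @param exclusionMinCoverage windows below this in ALL samples are
#'   excluded (default 1 fragment).
#' @param exclusionMode `"raw"` (default; unscaled fragment counts
#'   overlapping the window, the literal reading of "less than 1 fragment")
#'   or `"scaled"` (mean scaled per-base depth).
#' @param targetAutosomalTotal scaling target (default 1e7 autosomal
#'   fragments-equivalent).
#' @return validated list.
#' @export
mnaseConfig <- function(minFragmentLength = 140,
                        windowGrid = list(c(150, 50), c(500, 250),
                                          c(1000, 500), c(2000, 1000),
                                          c(5000, 2500)),
                        exclusionMinCoverage = 1,
                        exclusionMode = c("raw", "scaled"),
                        targetAutosomalTotal = 1e7) {
  stopifnot(minFragmentLength > 0)
  for (ws in windowGrid) stopifnot(length(ws) == 2, ws[2] <= ws[1])
  list(minFragmentLength = minFragmentLength, windowGrid = windowGrid,
       exclusionMinCoverage = exclusionMinCoverage,
       exclusionMode = match.arg(exclusionMode),
       targetAutosomalTotal = targetAutosomalTotal)
}

#' Filter MNase fragments by length
#'
#' Keeps fragments of length >= `minFragmentLength`, removing
#' subnucleosomal material (default < 140 bp).
#'
#' @param frags `GRanges` of fragments.
#' @param minFragmentLength bp cutoff (kept if `width >= cutoff`).
#' @return filtered `GRanges`.
#' @export
filterFragments <- function(frags, minFragmentLength = 140) {
  frags[BiocGenerics::width(frags) >= minFragmentLength]
}

## fully in-bounds tiling windows: starts 0, step s, last window end <= len
.tileWindows <- function(chromSizes, windowLength, step) {
  sl <- stats::setNames(as.integer(unlist(chromSizes)), names(chromSizes))
  grl <- lapply(names(chromSizes), function(nm) {
    len <- chromSizes[[nm]]
    if (len < windowLength)
      return(GRanges(seqlengths = sl))
    nWin <- floor((len - windowLength) / step) + 1
    starts0 <- (seq_len(nWin) - 1) * step
    GRanges(nm, IRanges(starts0 + 1, starts0 + windowLength),
            seqlengths = sl)
  })
  do.call(c, grl)
}

#' Tiled-window MNase fragment coverage
#'
#' Tiles each chromosome with fixed-width windows (only fully in-bounds
#' windows; starts at 0 every `step` bp) and computes, per sample, the mean
#' per-base scaled fragment depth over each window. Fragments are weighted
#' `target / (autosomal fragment count)` so every sample is normalized to
#' the same autosomal total; raw overlap counts are kept alongside for the
#' raw-count exclusion rule.
#'
#' @param frags a `GRanges` of (already length-filtered) fragments, or a
#'   named list of them (one per sample).
#' @param chromSizes named vector/list of chromosome lengths (bp).
#' @param windowLength,step tiling parameters (bp), default 150/50.
#' @param target autosomal scaling target (default 1e7).
#' @param sexChroms chromosome names excluded from the scaling denominator.
#' @return A [WindowOccupancyTable-class] (one column per sample).
#' @export
windowCoverage <- function(frags, chromSizes, windowLength = 150, step = 50,
                           target = 1e7, sexChroms = DEFAULT_SEX_CHROMS) {
  if (!is.list(frags)) frags <- list(sample1 = frags)
  if (is.null(names(frags)))
    names(frags) <- paste0("sample", seq_along(frags))
  chromSizes <- stats::setNames(as.numeric(unlist(chromSizes)),
                                names(unlist(chromSizes)))
  win <- .tileWindows(chromSizes, windowLength, step)
  cov <- matrix(0, length(win), length(frags),
                dimnames = list(NULL, names(frags)))
  raw <- cov
  for (i in seq_along(frags)) {
    fr <- frags[[i]]
    bad <- setdiff(unique(as.character(seqnames(fr))), names(chromSizes))
    if (length(bad))
      stop("fragment chromosome(s) absent from sizes: ",
           paste(bad, collapse = ", "))
    if (length(fr) == 0) next  # zero fragments: columns stay 0
    nAuto <- sum(!(as.character(seqnames(fr)) %in% sexChroms))
    if (nAuto == 0) stop("no autosomal fragments to scale by")
    weight <- target / nAuto
    rle <- GenomicRanges::coverage(
      GRanges(seqnames(fr), IRanges(
        pmax(BiocGenerics::start(fr), 1),
        pmin(BiocGenerics::end(fr), chromSizes[as.character(seqnames(fr))]))))
    cov[, i] <- .windowMeans(rle, win) * weight
    raw[, i] <- GenomicRanges::countOverlaps(win, fr)
  }
  new("WindowOccupancyTable", windows = win, coverage = cov, rawCounts = raw,
      excluded = logical(0),
      params = list(window_length = windowLength, step = step,
                    target = target, sex_chroms = sexChroms))
}

#' Flag low-coverage windows across samples
#'
#' A window is excluded iff its coverage is below the threshold in ALL
#' samples (such windows mark genomic regions of very low mappability).
#' By default "coverage" is the raw fragment overlap count ("less than 1
#' fragment covering them"); `mode = "scaled"` uses the scaled per-base
#' mean depth instead. Both the window-wise excluded fraction and the
#' genomic-bp fraction of the union of excluded windows are reported, since
#' a genome-fraction summary can mean either.
#'
#' @param table a multi-sample [WindowOccupancyTable-class].
#' @param minCoverage exclusion threshold (default 1).
#' @param mode `"raw"` (default) or `"scaled"`.
#' @return the table with `excluded` flags set and
#'   `params$fraction_excluded` = list(window-wise, bp-union) recorded.
#' @export
excludeLowCoverage <- function(table, minCoverage = 1,
                               mode = c("raw", "scaled")) {
  stopifnot(is(table, "WindowOccupancyTable"))
  mode <- match.arg(mode)
  m <- if (mode == "raw") rawFragmentCounts(table) else occupancyMatrix(table)
  if (ncol(m) == 0) stop("no samples in table")
  excluded <- rowSums(m < minCoverage) == ncol(m)
  win <- occupancyWindows(table)
  genomeBp <- sum(as.numeric(GenomeInfoDb::seqlengths(win)), na.rm = TRUE)
  bpUnion <- sum(as.numeric(BiocGenerics::width(
    GenomicRanges::reduce(win[excluded]))))
  table@excluded <- unname(excluded)
  table@params$exclusion <- list(
    min_coverage = minCoverage, mode = mode,
    fraction_excluded_windows = mean(excluded),
    fraction_excluded_bp = if (genomeBp > 0) bpUnion / genomeBp else NA_real_)
  table
}

#' Autosome-vs-X occupancy density summaries
#'
#' Quantiles and histograms of window coverage over non-excluded windows,
#' per sample and chromosome class, plus the median X/A ratio per sample.
#'
#' @param table a [WindowOccupancyTable-class] (run [excludeLowCoverage()]
#'   first; with no flags set, all windows are used).
#' @param sexChroms chromosome names forming the X class.
#' @param probs quantiles to report.
#' @param breaks histogram break count.
#' @return list: `summary` (data.frame sample x class quantiles),
#'   `median_xa_ratio` (named numeric per sample), `histograms` (list).
#' @export
occupancyDensitySummary <- function(table, sexChroms = NULL,
                                    probs = c(0.05, 0.25, 0.5, 0.75, 0.95),
                                    breaks = 50) {
  stopifnot(is(table, "WindowOccupancyTable"))
  if (is.null(sexChroms))
    sexChroms <- table@params$sex_chroms %||% DEFAULT_SEX_CHROMS
  keep <- if (length(table@excluded)) !table@excluded
  else rep(TRUE, length(table@windows))
  isX <- as.character(seqnames(table@windows)) %in% sexChroms
  cov <- occupancyMatrix(table)
  if (is.null(colnames(cov)))
    colnames(cov) <- paste0("sample", seq_len(ncol(cov)))
  classes <- list(autosome = keep & !isX, X = keep & isX)
  for (nm in names(classes))
    if (!any(classes[[nm]]))
      stop("no kept windows in class ", nm)
  rows <- list(); hists <- list(); ratio <- numeric(ncol(cov))
  for (i in seq_len(ncol(cov))) {
    med <- c(autosome = NA_real_, X = NA_real_)
    for (nm in names(classes)) {
      v <- cov[classes[[nm]], i]
      qs <- stats::quantile(v, probs)
      med[nm] <- stats::median(v)
      rows[[length(rows) + 1]] <- data.frame(
        sample = colnames(cov)[i], class = nm, n_windows = length(v),
        t(as.matrix(qs)), check.names = FALSE)
      hists[[paste(colnames(cov)[i], nm, sep = ".")]] <-
        graphics::hist(v, breaks = breaks, plot = FALSE)
    }
    ratio[i] <- med["X"] / med["autosome"]
  }
  names(ratio) <- colnames(cov)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  list(summary = out, median_xa_ratio = ratio, histograms = hists)
}

#' Run the multi-scale MNase window analysis
#'
#' Applies [filterFragments()], then for each `(window, step)` pair in the
#' config grid computes [windowCoverage()] across samples and
#' [excludeLowCoverage()].
#'
#' @param fragsList named list of `GRanges` fragment sets (one per sample).
#' @param chromSizes named chromosome lengths.
#' @param config from [mnaseConfig()].
#' @return named list of [WindowOccupancyTable-class], one per window scale
#'   (`"w150_s50"`, ...).
#' @export
mnaseOccupancyAnalysis <- function(fragsList, chromSizes,
                                   config = mnaseConfig()) {
  filtered <- lapply(fragsList, filterFragments, config$minFragmentLength)
  out <- lapply(config$windowGrid, function(ws) {
    tab <- windowCoverage(filtered, chromSizes, windowLength = ws[1],
                          step = ws[2], target = config$targetAutosomalTotal)
    excludeLowCoverage(tab, config$exclusionMinCoverage,
                       config$exclusionMode)
  })
  names(out) <- vapply(config$windowGrid,
                       function(ws) sprintf("w%d_s%d", ws[1], ws[2]), "")
  out
}
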