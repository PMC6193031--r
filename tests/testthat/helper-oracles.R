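## Independent oracles and small fixture builders. Oracles here are written
## against the definitions, not against the package's interval code paths.

## --- brute-force per-base coverage ------------------------------------

## expand a bedGraph-like data.frame (chrom, start0, end0, value) into a
## per-base vector for one chromosome (0-based positions 0..len-1)
perBaseVector <- function(df, chrom, len) {
  v <- numeric(len)
  d <- df[df$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(d))) {
    idx <- seq(d$start0[i] + 1, d$end0[i])
    v[idx] <- v[idx] + d$value[i]
  }
  v
}

## brute-force mean over a 0-based half-open window, zeros counted,
## clipped to [0, len)
bruteMean <- function(df, chrom, s0, e0, len) {
  s0 <- max(s0, 0); e0 <- min(e0, len)
  if (e0 <= s0) return(NA_real_)
  v <- perBaseVector(df, chrom, len)
  mean(v[(s0 + 1):e0])
}

bruteTotal <- function(df, chroms, len) {
  sum(vapply(chroms, function(cc) sum(perBaseVector(df, cc, len)), numeric(1)))
}

## build a CoverageTrack from the same data.frame
trackFromDf <- function(df, sexChroms = c("X", "chrX"), seqlen = NULL) {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start0 + 1, df$end0),
                               score = df$value)
  if (!is.null(seqlen)) GenomeInfoDb::seqlengths(gr) <- seqlen
  CoverageTrack(gr, scaleState = "raw", sexChroms = sexChroms)
}

## random non-overlapping step track on one chromosome
randomTrackDf <- function(chrom, len, nIntervals, maxVal = 10) {
  cuts <- sort(sample(0:len, nIntervals + 1))
  cuts <- unique(cuts)
  data.frame(chrom = chrom, start0 = cuts[-length(cuts)], end0 = cuts[-1],
             value = round(stats::runif(length(cuts) - 1, 0, maxVal), 3))
}

## gene GRanges builder (0-based half-open inputs)
makeGenes <- function(chrom, start0, end0, strand = "+",
                      id = NULL, tlen = NULL, seqlen = NULL,
                      sexChroms = c("X", "chrX")) {
  n <- length(start0)
  if (is.null(id)) id <- paste0("g", seq_len(n))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                               strand = rep(strand, length.out = n))
  gr$gene_id <- id
  gr$transcript_length <- if (is.null(tlen)) as.numeric(end0 - start0) else tlen
  gr$is_autosomal <- !(as.character(GenomicRanges::seqnames(gr)) %in% sexChroms)
  names(gr) <- id
  if (!is.null(seqlen)) GenomeInfoDb::seqlengths(gr) <- seqlen
  gr
}

## MarkSignalTable builder at a given stage
makeSignal <- function(values, stage = "log2p1", isAutosomal = NULL,
                       mark = "markA") {
  if (is.null(isAutosomal)) isAutosomal <- rep(TRUE, length(values))
  m <- matrix(values, ncol = 1,
              dimnames = list(names(values) %||%
                                paste0("g", seq_along(values)), mark))
  new("MarkSignalTable", signal = m, stage = stage,
      windowMode = "gene_body", isAutosomal = isAutosomal,
      provenance = list())
}
`%||%` <- function(a, b) if (is.null(a)) b else a

## --- statistics oracles -----------------------------------------------

## hypergeometric upper tail P[X >= k] by full enumeration of the
## choose(N, n) equally likely draws
hyperEnumOracle <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))  # the empty draw overlaps by 0
  draws <- utils::combn(N, n)
  inK <- draws <= K  # items 1..K are the "marked" ones
  overlaps <- colSums(matrix(inK, nrow = n))
  mean(overlaps >= k)
}

## BH step-up by the textbook definition: find the largest j with
## p_(j) <= j q / m; adjusted value = min over j >= rank of p_(j) m / j
bhStepUpOracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

## Mann-Whitney U by direct pair counting
uOracle <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

## --- shared simulation runner -----------------------------------------

## run the sperm ChIP -> z-score -> quadrant pipeline for one seed and
## return recovery counts of the planted multivalent class
quadrantRecoveryRun <- function(seed) {
  cfg <- simConfig(seed = seed)
  sim <- simulateGenome(cfg)
  z <- lapply(c(H3K36me3 = "H3K36me3", H3K27me3 = "H3K27me3"), function(mk) {
    track <- simulateChipTracks(sim$genes, sim$truth, cfg, "sperm", mk)
    scaled <- scaleToAutosomalTarget(track)
    zscoreAgainstAutosomes(logTransform(geneMeanCoverage(
      scaled, sim$genes, mark = mk)))
  })
  qc <- classifyQuadrants(z$H3K36me3, z$H3K27me3)
  planted <- names(which(plantedMultivalent(sim$truth)))
  called <- names(which(isMultivalent(qc)))
  c(tp = length(intersect(called, planted)),
    fp = length(setdiff(called, planted)),
    fn = length(setdiff(planted, called)))
}
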