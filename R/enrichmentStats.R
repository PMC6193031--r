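## enrichment_stats: hypergeometric gene-set overlap tests, Mann-Whitney
## shift tests on log2-fold-change distributions, and the Benjamini-Hochberg
## step-up adjustment.

#' Hypergeometric gene-set overlap test
#'
#' One-sided enrichment p-value `P[X >= k]` for the overlap `k` of two sets
#' of sizes K and n drawn from a universe of size N, X hypergeometric. The
#' tail is evaluated in log space so extreme overlaps (p < 1e-300) are still
#' reported via `log10_p`.
#'
#' @param universe [GeneList-class] or character vector: the gene universe
#'   (typically the genes tested in both comparisons).
#' @param setA,setB [GeneList-class] or character vectors, both subsets of
#'   the universe (violations are an error listing offenders).
#' @return An object of class `"htest"` with `p.value`, `log10_p`, and the
#'   counts N, K, n, k in `parameter`.
#' @export
hypergeometricOverlap <- function(universe, setA, setB) {
  u <- if (is(universe, "GeneList")) geneIds(universe) else universe
  a <- if (is(setA, "GeneList")) geneIds(setA) else setA
  b <- if (is(setB, "GeneList")) geneIds(setB) else setB
  if (!length(u)) stop("empty universe")
  for (s in list(A = a, B = b)) {
    out <- setdiff(s, u)
    if (length(out))
      stop("set member(s) outside the universe: ",
           paste(utils::head(out, 5), collapse = ", "))
  }
  N <- length(u); K <- length(a); n <- length(b)
  k <- length(intersect(a, b))
  ## upper tail P[X >= k]; phyper is P[X > q], so q = k - 1
  logP <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  structure(list(
    statistic = c(overlap = k),
    parameter = c(N = N, K = K, n = n),
    p.value = exp(logP),
    log10_p = logP / log(10),
    alternative = "greater",
    method = "Hypergeometric gene-set overlap test",
    data.name = sprintf("overlap %d of %d x %d in universe %d", k, K, n, N)
  ), class = "htest")
}

## midranks of a pooled vector
.midranks <- function(x) rank(x, ties.method = "average")

## Mann-Whitney U of x against y (U = #{(i,j): x_i > y_j} + ties/2)
.uStatistic <- function(x, y) {
  r <- .midranks(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney U shift test
#'
#' Rank-sum test of whether `valuesSubset` is shifted relative to
#' `valuesAll` — e.g. the log2 fold changes of a gene set against all genes
#' (the subset may be contained in the background; `background =
#' "complement"` removes it first). Uses midranks for ties; the p-value is
#' exact by enumeration of all labelings when `n1 + n2 <= 12` (ties
#' included), and a normal approximation with tie correction and continuity
#' correction otherwise.
#'
#' @param valuesSubset,valuesAll numeric vectors (non-empty).
#' @param alternative `"two.sided"` (default), `"greater"` (subset shifted
#'   up), or `"less"`.
#' @param background `"all"` (default; compare against the vector as given,
#'   the subset-vs-all-genes reading) or `"complement"` (drop the subset's
#'   values from the background first, matching by value with multiplicity).
#' @param exactLimit combined size at or below which the exact enumeration
#'   is used (default 12).
#' @return An object of class `"htest"`: `statistic` (U), `p.value`,
#'   sample sizes in `parameter`, and the method used.
#' @export
mannWhitneyShift <- function(valuesSubset, valuesAll,
                             alternative = c("two.sided", "greater", "less"),
                             background = c("all", "complement"),
                             exactLimit = 12) {
  alternative <- match.arg(alternative)
  background <- match.arg(background)
  x <- as.numeric(valuesSubset)
  y <- as.numeric(valuesAll)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (background == "complement") {
    for (v in x) {
      i <- match(v, y)
      if (!is.na(i)) y <- y[-i]
    }
    if (!length(y)) stop("background empty after removing the subset")
  }
  n1 <- length(x); n2 <- length(y)
  U <- .uStatistic(x, y)
  allSame <- length(unique(c(x, y))) == 1
  if (allSame) {
    warning("all values identical in both samples; p = 1")
    p <- 1
    method <- "Mann-Whitney U test (degenerate)"
  } else if (n1 + n2 <= exactLimit) {
    ## exact: U over all choose(n1+n2, n1) assignments of the pooled values
    pooled <- c(x, y)
    r <- .midranks(pooled)
    combos <- utils::combn(n1 + n2, n1)
    u0 <- n1 * (n1 + 1) / 2
    Us <- colSums(matrix(r[combos], nrow = n1)) - u0
    mu <- n1 * n2 / 2
    p <- switch(alternative,
                greater = mean(Us >= U),
                less = mean(Us <= U),
                two.sided = mean(abs(Us - mu) >= abs(U - mu)))
    method <- "Mann-Whitney U test (exact enumeration)"
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    tie <- table(c(x, y))
    tieCorr <- sum(tie^3 - tie) / (nt * (nt - 1))
    sigma <- sqrt(n1 * n2 / 12 * (nt + 1 - tieCorr))
    cc <- 0.5  # continuity correction
    zg <- (U - mu - cc) / sigma
    zl <- (U - mu + cc) / sigma
    p <- switch(alternative,
                greater = stats::pnorm(zg, lower.tail = FALSE),
                less = stats::pnorm(zl),
                two.sided = min(1, 2 * min(stats::pnorm(zg, lower.tail = FALSE),
                                           stats::pnorm(zl))))
    method <- "Mann-Whitney U test (normal approximation, tie-corrected)"
  }
  structure(list(
    statistic = c(U = U),
    parameter = c(n1 = n1, n2 = n2),
    p.value = p,
    alternative = alternative,
    method = method,
    data.name = "valuesSubset vs valuesAll"
  ), class = "htest")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `adj[i] = min_{j >= i} min(1, p_(j) * m / j)` on the sorted p-values,
#' mapped back to input order. NAs are left NA and do not count toward m.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted values, same order as the input.
#' @export
benjaminiHochberg <- function(pvalues) {
  p <- as.numeric(pvalues)
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(out)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  m <- length(ok)
  ord <- order(p[ok])
  ranked <- p[ok][ord] * m / seq_len(m)
  adj <- rev(cummin(rev(pmin(ranked, 1))))
  out[ok][ord] <- adj
  out
}
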