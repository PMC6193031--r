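## synthetic_data: a seeded generator for genomes, marked ChIP coverage
## tracks, germline expression counts and MNase fragments, with planted
## ground truth. The generator's defaults state the world the analysis
## assumes: alternating active/repressive autosomal domains, multivalent
## marking of spermatogenesis-specific genes in sperm, class-structured NB
## expression across germline types, nucleosomal fragment-length mixtures
## with subnucleosomal contamination, and halved X dosage in sperm.

GENE_CLASSES <- c("spermatogenesis_specific", "oogenesis_enriched",
                  "sex_independent", "silent")
CELL_TYPES <- c("sperm", "oocyte", "embryo")
MARKS <- c("H3K4me3", "H3K36me3", "H3K27me3")

#' SimConfig: parameters of the synthetic world
#'
#' Defaults encode the biology the analysis assumes. Class proportions
#' (0.08 / 0.10 / 0.12 / 0.70) mirror the relative sizes of the
#' spermatogenesis-specific (~1300), oogenesis-enriched (~2000) and
#' sex-independent (~2100) sets among ~20,000 coding genes, with the large
#' remainder silent in germlines; with spermatogenesis plus silent genes
#' carrying H3K27me3, >= 70% of genes bear the repressive mark, which is what
#' makes a 30th-percentile autosomal baseline a sensible zero point.
#' Spermatogenesis-specific genes are never planted on the X (germline X
#' silencing). Mark intensities are in arbitrary coverage units over a
#' uniform background; expression means are counts per kb of transcript at
#' nominal depth.
#'
#' @slot seed integer; fixes all outputs bit-for-bit.
#' @slot nAutosomes,chromLength,nGenesPerChrom genome layout.
#' @slot classProportions named proportions over the four gene classes
#'   (must sum to 1).
#' @slot markIntensity data.frame (class, cell_type, mark, mean): mean
#'   signal over background for marked gene bodies/promoters; absent rows
#'   mean unmarked.
#' @slot k4BodyIntensitySperm gene-body H3K4me3 level added for
#'   spermatogenesis-specific genes in sperm only.
#' @slot background mean of the uniform per-bin background signal.
#' @slot noiseDispersion squared CV of the multiplicative gamma noise on
#'   marked signal (0 = noiseless).
#' @slot exprMeans data.frame (class, germline_type, mean): NB mean counts
#'   per kb of transcript.
#' @slot exprDispersion NB dispersion of simulated counts (0 = Poisson).
#' @slot nReplicates replicates per sample condition.
#' @slot libraryFactorSd sd of the per-sample log-normal library factor.
#' @slot xPloidyRatioSperm X-chromosome dosage in sperm relative to
#'   autosomes (0.5: one X against diploid-equivalent autosome coverage).
#' @slot fragLenMean,fragLenSd nucleosomal MNase fragment length (bp).
#' @slot subnucleosomalFraction fraction of fragments drawn from
#'   Uniform(100, 139) bp.
#' @slot nFragments MNase fragments per sample.
#' @slot desertFraction fraction of each chromosome planted as
#'   zero-coverage low-mappability deserts.
#' @slot desertsPerChrom number of desert intervals per chromosome.
#' @export
setClass("SimConfig",
  representation(
    seed = "numeric", nAutosomes = "numeric", chromLength = "numeric",
    nGenesPerChrom = "numeric", classProportions = "numeric",
    markIntensity = "data.frame", k4BodyIntensitySperm = "numeric",
    background = "numeric", noiseDispersion = "numeric",
    exprMeans = "data.frame", exprDispersion = "numeric",
    nReplicates = "numeric", libraryFactorSd = "numeric",
    xPloidyRatioSperm = "numeric", fragLenMean = "numeric",
    fragLenSd = "numeric", subnucleosomalFraction = "numeric",
    nFragments = "numeric", desertFraction = "numeric",
    desertsPerChrom = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character(0)
  p <- object@classProportions
  if (!setequal(names(p), GENE_CLASSES))
    msg <- c(msg, "classProportions must be named by the four gene classes")
  else if (abs(sum(p) - 1) > 1e-9)
    msg <- c(msg, "classProportions must sum to 1")
  if (any(p < 0)) msg <- c(msg, "classProportions must be >= 0")
  if (any(object@markIntensity$mean < 0) || any(object@exprMeans$mean < 0))
    msg <- c(msg, "all means must be >= 0")
  if (object@noiseDispersion < 0 || object@exprDispersion < 0)
    msg <- c(msg, "dispersions must be >= 0")
  if (object@subnucleosomalFraction < 0 || object@subnucleosomalFraction > 1)
    msg <- c(msg, "subnucleosomalFraction must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

## Marking rules of the stated world: which class bears which mark where.
## Sperm: spermatogenesis-specific genes are multivalent (H3K36me3 +
## H3K27me3 + H3K4me3 incl. gene body); oogenesis and sex-independent genes
## bear only active marks; silent genes sit in weaker broad H3K27me3 domains.
## Oocytes and embryos: spermatogenesis genes bear only H3K27me3.
.defaultMarkIntensity <- function() {
  rbind(
    expand.grid(class = c("spermatogenesis_specific", "oogenesis_enriched",
                          "sex_independent"),
                cell_type = "sperm", mark = c("H3K36me3", "H3K4me3"),
                mean = 8, stringsAsFactors = FALSE),
    data.frame(class = "spermatogenesis_specific", cell_type = "sperm",
               mark = "H3K27me3", mean = 6),
    data.frame(class = "silent", cell_type = "sperm",
               mark = "H3K27me3", mean = 3),
    expand.grid(class = c("oogenesis_enriched", "sex_independent"),
                cell_type = c("oocyte", "embryo"),
                mark = c("H3K36me3", "H3K4me3"),
                mean = 8, stringsAsFactors = FALSE),
    expand.grid(class = c("spermatogenesis_specific", "silent"),
                cell_type = c("oocyte", "embryo"), mark = "H3K27me3",
                mean = NA_real_, stringsAsFactors = FALSE) |>
      transform(mean = ifelse(class == "spermatogenesis_specific", 6, 3))
  )
}

.defaultExprMeans <- function() {
  rbind(
    data.frame(class = "spermatogenesis_specific",
               germline_type = c("spermatogenic", "oogenic"),
               mean = c(30000, 1)),
    data.frame(class = "oogenesis_enriched",
               germline_type = c("spermatogenic", "oogenic"),
               mean = c(15000, 40000)),
    data.frame(class = "sex_independent",
               germline_type = c("spermatogenic", "oogenic"),
               mean = c(15000, 15000)),
    data.frame(class = "silent",
               germline_type = c("spermatogenic", "oogenic"),
               mean = c(1, 1))
  )
}

#' Construct a SimConfig
#'
#' @param seed RNG seed fixing all outputs.
#' @param nAutosomes,chromLength,nGenesPerChrom genome layout (defaults 5
#'   autosomes of 1 Mb with 200 genes each, plus an X chromosome).
#' @param classProportions,markIntensity,k4BodyIntensitySperm,background,noiseDispersion
#'   ChIP world; see [SimConfig-class].
#' @param exprMeans,exprDispersion,nReplicates,libraryFactorSd expression
#'   world.
#' @param xPloidyRatioSperm,fragLenMean,fragLenSd,subnucleosomalFraction,nFragments,desertFraction,desertsPerChrom
#'   MNase world.
#' @return A validated [SimConfig-class].
#' @export
simConfig <- function(seed = 1L,
                      nAutosomes = 5, chromLength = 1e6, nGenesPerChrom = 200,
                      classProportions = c(spermatogenesis_specific = 0.08,
                                           oogenesis_enriched = 0.10,
                                           sex_independent = 0.12,
                                           silent = 0.70),
                      markIntensity = .defaultMarkIntensity(),
                      k4BodyIntensitySperm = 4,
                      background = 0.5, noiseDispersion = 0.2,
                      exprMeans = .defaultExprMeans(), exprDispersion = 0.1,
                      nReplicates = 3, libraryFactorSd = 0.1,
                      xPloidyRatioSperm = 0.5,
                      fragLenMean = 165, fragLenSd = 15,
                      subnucleosomalFraction = 0.1, nFragments = 1e6,
                      desertFraction = 0.02, desertsPerChrom = 3) {
  new("SimConfig", seed = seed, nAutosomes = nAutosomes,
      chromLength = chromLength, nGenesPerChrom = nGenesPerChrom,
      classProportions = classProportions, markIntensity = markIntensity,
      k4BodyIntensitySperm = k4BodyIntensitySperm, background = background,
      noiseDispersion = noiseDispersion, exprMeans = exprMeans,
      exprDispersion = exprDispersion, nReplicates = nReplicates,
      libraryFactorSd = libraryFactorSd,
      xPloidyRatioSperm = xPloidyRatioSperm, fragLenMean = fragLenMean,
      fragLenSd = fragLenSd, subnucleosomalFraction = subnucleosomalFraction,
      nFragments = nFragments, desertFraction = desertFraction,
      desertsPerChrom = desertsPerChrom)
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: seed %d, %d autosome(s) + X of %g bp, %d genes/chrom\n",
              as.integer(object@seed), as.integer(object@nAutosomes),
              object@chromLength, as.integer(object@nGenesPerChrom)))
})

#' GroundTruth: planted state of a simulated genome
#'
#' @slot geneClass named character: planted class per gene.
#' @slot markState data.frame (gene, cell_type, mark, marked): planted
#'   marked/unmarked state.
#' @slot multivalentSperm named logical: genes planted with both active and
#'   repressive marks in sperm (the spermatogenesis-specific class).
#' @slot deserts `GRanges` of planted zero-coverage (low-mappability)
#'   regions; a genome property shared by all MNase samples.
#' @export
setClass("GroundTruth",
  representation(geneClass = "character", markState = "data.frame",
                 multivalentSperm = "logical", deserts = "GRanges"))

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d genes\n", length(object@geneClass)))
  print(table(object@geneClass))
})

#' @rdname accessors
#' @export
setGeneric("plantedClass", function(x) standardGeneric("plantedClass"))

#' @rdname accessors
#' @export
setMethod("plantedClass", "GroundTruth", function(x) x@geneClass)

#' @rdname accessors
#' @export
setGeneric("plantedMultivalent", function(x) standardGeneric("plantedMultivalent"))

#' @rdname accessors
#' @export
setMethod("plantedMultivalent", "GroundTruth", function(x) x@multivalentSperm)

#' @rdname accessors
#' @export
setGeneric("plantedMarkState", function(x) standardGeneric("plantedMarkState"))

#' @rdname accessors
#' @export
setMethod("plantedMarkState", "GroundTruth", function(x) x@markState)

#' @rdname accessors
#' @export
setGeneric("plantedDeserts", function(x) standardGeneric("plantedDeserts"))

#' @rdname accessors
#' @export
setMethod("plantedDeserts", "GroundTruth", function(x) x@deserts)

.simChromNames <- function(config) {
  c(paste0("chr", as.character(utils::as.roman(seq_len(config@nAutosomes)))),
    "chrX")
}

## Low-mappability deserts are a property of the genome, not of a sample:
## they are derived from the config seed alone so every simulated MNase
## sample shares them (the all-samples exclusion rule depends on this).
.mappabilityDeserts <- function(config) {
  chroms <- .simChromNames(config)
  L <- config@chromLength
  k <- config@desertsPerChrom
  dlen <- floor(L * config@desertFraction / k)
  sl <- stats::setNames(rep(L, length(chroms)), chroms)
  .withSeed(.subSeed(config@seed, 777), {
    grl <- lapply(chroms, function(nm) {
      seg <- floor(L / k)
      starts0 <- vapply(seq_len(k) - 1L, function(i)
        i * seg + floor(stats::runif(1, 0, seg - dlen)), numeric(1))
      GRanges(nm, IRanges(starts0 + 1, starts0 + dlen), seqlengths = sl)
    })
    do.call(c, grl)
  })
}

#' Simulate a gene-annotated genome with planted classes
#'
#' Tiles non-overlapping genes with intergenic gaps along each autosome and
#' the X. Gene classes are drawn from `classProportions`;
#' spermatogenesis-specific genes are planted only on autosomes (germline X
#' silencing). Ground truth records the planted class, the planted per
#' cell-type/mark marked state implied by the mark-intensity rules, the
#' multivalent-in-sperm flag, and the shared low-mappability deserts.
#'
#' @param config a [SimConfig-class].
#' @return `list(genes = GRanges, truth = GroundTruth)`; `genes` carries
#'   `gene_id`, `transcript_length`, `is_autosomal` and seqlengths.
#' @export
simulateGenome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  chroms <- .simChromNames(config)
  L <- config@chromLength
  nG <- config@nGenesPerChrom
  sl <- stats::setNames(rep(L, length(chroms)), chroms)
  .withSeed(.subSeed(config@seed, 1), {
    perChrom <- lapply(chroms, function(nm) {
      spans <- round(stats::runif(nG, 800, 2500))
      gaps <- round(stats::runif(nG, 500, 2000))
      starts0 <- cumsum(gaps) + cumsum(c(0, spans[-nG]))
      ends0 <- starts0 + spans
      if (ends0[nG] > L)
        stop(sprintf("genes cannot fit chromosome %s at requested density", nm))
      prop <- config@classProportions
      if (nm == "chrX") {
        prop["spermatogenesis_specific"] <- 0
        prop <- prop / sum(prop)
      }
      cls <- sample(names(prop), nG, replace = TRUE, prob = prop)
      strand <- sample(c("+", "-"), nG, replace = TRUE)
      tlen <- pmax(1, round(spans * stats::runif(nG, 0.5, 0.9)))
      gr <- GRanges(nm, IRanges(starts0 + 1, ends0), strand = strand,
                    seqlengths = sl)
      gr$gene_id <- sprintf("%s_g%04d", nm, seq_len(nG))
      gr$transcript_length <- as.numeric(tlen)
      gr$is_autosomal <- nm != "chrX"
      gr$class <- cls
      gr
    })
    genes <- do.call(c, perChrom)
    names(genes) <- genes$gene_id
    cls <- stats::setNames(genes$class, genes$gene_id)
    genes$class <- NULL
    mi <- config@markIntensity
    markState <- expand.grid(gene = genes$gene_id, cell_type = CELL_TYPES,
                             mark = MARKS, stringsAsFactors = FALSE)
    key <- paste(cls[markState$gene], markState$cell_type, markState$mark)
    marked <- key %in% paste(mi$class, mi$cell_type, mi$mark)[mi$mean > 0]
    markState$marked <- marked
    truth <- new("GroundTruth", geneClass = cls, markState = markState,
                 multivalentSperm = stats::setNames(
                   cls == "spermatogenesis_specific", genes$gene_id),
                 deserts = .mappabilityDeserts(config))
    list(genes = genes, truth = truth)
  })
}

#' Simulate a ChIP-seq coverage track
#'
#' Emits 50 bp resolution signal: uniform background plus, over the regions
#' of genes whose planted class bears the mark in the given cell type, the
#' configured class mean under multiplicative gamma noise
#' (shape = 1/noiseDispersion, mean 1). H3K36me3 and H3K27me3 cover gene
#' bodies; H3K4me3 is emitted over promoters (TSS +/- 500 bp) of expressed
#' classes and additionally over gene bodies of spermatogenesis-specific
#' genes in sperm. X-chromosome signal is multiplied by `xPloidyRatioSperm`
#' in sperm.
#'
#' @param genes,truth from [simulateGenome()].
#' @param config a [SimConfig-class].
#' @param cellType `"sperm"`, `"oocyte"` or `"embryo"`.
#' @param mark `"H3K4me3"`, `"H3K36me3"` or `"H3K27me3"`.
#' @return A raw-scale [CoverageTrack-class].
#' @export
simulateChipTracks <- function(genes, truth, config, cellType, mark) {
  if (!cellType %in% CELL_TYPES)
    stop("unknown cell type: ", cellType)
  if (!mark %in% MARKS)
    stop("unknown mark: ", mark)
  binW <- 50L
  chroms <- GenomeInfoDb::seqlevels(genes)
  L <- config@chromLength
  offset <- 100 + match(cellType, CELL_TYPES) * 10 + match(mark, MARKS)
  cls <- plantedClass(truth)
  mi <- config@markIntensity
  mi <- mi[mi$cell_type == cellType & mi$mark == mark & mi$mean > 0, ,
           drop = FALSE]
  .withSeed(.subSeed(config@seed, offset), {
    perChrom <- lapply(chroms, function(nm) {
      nb <- as.integer(ceiling(L / binW))
      val <- stats::runif(nb, 0, 2 * config@background)
      binStart <- (seq_len(nb) - 1L) * binW + 1L
      bins <- GRanges(nm, IRanges(binStart, pmin(binStart + binW - 1L, L)),
                      seqlengths = GenomeInfoDb::seqlengths(genes))
      g <- genes[as.character(seqnames(genes)) == nm]
      if (length(g) && nrow(mi)) {
        for (i in seq_len(nrow(mi))) {
          sel <- g[cls[g$gene_id] == mi$class[i]]
          if (!length(sel)) next
          regions <- .markRegions(sel, mark)
          hit <- IRanges::findOverlaps(bins, regions)
          idx <- unique(S4Vectors::queryHits(hit))
          val[idx] <- val[idx] + mi$mean[i] * .gammaNoise(length(idx), config)
        }
      }
      if (mark == "H3K4me3" && cellType == "sperm" &&
          config@k4BodyIntensitySperm > 0) {
        sel <- g[cls[g$gene_id] == "spermatogenesis_specific"]
        if (length(sel)) {
          hit <- IRanges::findOverlaps(bins, sel)
          idx <- unique(S4Vectors::queryHits(hit))
          val[idx] <- val[idx] +
            config@k4BodyIntensitySperm * .gammaNoise(length(idx), config)
        }
      }
      if (nm %in% DEFAULT_SEX_CHROMS && cellType == "sperm")
        val <- val * config@xPloidyRatioSperm
      bins$score <- val
      bins
    })
    gr <- do.call(c, perChrom)
    CoverageTrack(gr, scaleState = "raw")
  })
}

.gammaNoise <- function(n, config) {
  nd <- config@noiseDispersion
  if (nd <= 0) rep(1, n) else stats::rgamma(n, shape = 1 / nd, scale = nd)
}

## region of a gene that carries a given mark: gene body for the body marks,
## strand-aware TSS +/- 500 bp for the promoter mark H3K4me3
.markRegions <- function(genes, mark) {
  if (mark != "H3K4me3") return(GenomicRanges::granges(genes))
  minus <- as.character(strand(genes)) == "-"
  tss0 <- ifelse(minus, BiocGenerics::end(genes), BiocGenerics::start(genes) - 1L)
  GRanges(seqnames(genes), IRanges(pmax(tss0 - 500, 0) + 1, tss0 + 500))
}

#' Simulate germline expression counts
#'
#' Negative-binomial counts with mean
#' `exprMeans[class, germline] x transcript length (kb) x library factor`,
#' independent across replicates, with the per-sample library factor drawn
#' log-normal(0, `libraryFactorSd`). Two male genotypes (`wild_type`,
#' `him_8`) of spermatogenic germlines are emitted alongside wild-type
#' oogenic germlines, so genotype-intersection gene-set rules are
#' exercisable.
#'
#' @param genes,truth from [simulateGenome()].
#' @param config a [SimConfig-class].
#' @return An [ExpressionTable-class] with `transcript_length` and
#'   `is_autosomal` in `rowData`.
#' @export
simulateExpression <- function(genes, truth, config) {
  cls <- plantedClass(truth)
  em <- config@exprMeans
  meanOf <- function(germline) {
    m <- em$mean[match(paste(cls[genes$gene_id], germline),
                       paste(em$class, em$germline_type))]
    m * genes$transcript_length / 1000
  }
  conditions <- rbind(
    expand.grid(germline_type = "spermatogenic",
                genotype = c("wild_type", "him_8"),
                replicate = seq_len(config@nReplicates),
                stringsAsFactors = FALSE),
    expand.grid(germline_type = "oogenic", genotype = "wild_type",
                replicate = seq_len(config@nReplicates),
                stringsAsFactors = FALSE)
  )
  .withSeed(.subSeed(config@seed, 5000), {
    counts <- sapply(seq_len(nrow(conditions)), function(i) {
      lf <- stats::rlnorm(1, 0, config@libraryFactorSd)
      mu <- meanOf(conditions$germline_type[i]) * lf
      if (config@exprDispersion <= 0) stats::rpois(length(mu), mu)
      else stats::rnbinom(length(mu), mu = mu, size = 1 / config@exprDispersion)
    })
    rownames(counts) <- genes$gene_id
    colnames(counts) <- sprintf("%s_%s_r%d",
                                substr(conditions$germline_type, 1, 5),
                                conditions$genotype, conditions$replicate)
    ExpressionTable(counts, conditions,
                    geneInfo = DataFrame(
                      transcript_length = genes$transcript_length,
                      is_autosomal = genes$is_autosomal,
                      row.names = genes$gene_id))
  })
}

#' Simulate MNase-seq fragments
#'
#' Fragment midpoints are uniform over the non-desert genome (deserts are
#' planted zero-coverage regions shared by all samples, derived from the
#' config seed alone). Lengths are Normal(`fragLenMean`, `fragLenSd`)
#' truncated at 100 bp, with `subnucleosomalFraction` of fragments drawn
#' from Uniform(100, 139) bp. X-chromosome fragment density is scaled by
#' `xPloidyRatioSperm` in sperm.
#'
#' @param genes from [simulateGenome()] (provides chromosome sizes).
#' @param config a [SimConfig-class].
#' @param cellType `"sperm"`, `"oocyte"` or `"embryo"`.
#' @param replicate integer; distinct replicates get independent fragments.
#' @return `GRanges` of fragments.
#' @export
simulateMnase <- function(genes, config, cellType, replicate = 1L) {
  if (!cellType %in% CELL_TYPES) stop("unknown cell type: ", cellType)
  chromLens <- .chromLens(genes)
  deserts <- .mappabilityDeserts(config)
  n <- config@nFragments
  offset <- 9000 + match(cellType, CELL_TYPES) * 100 + replicate
  .withSeed(.subSeed(config@seed, offset), {
    ## chromosome weights: accessible length, X down-weighted in sperm
    open <- lapply(names(chromLens), function(nm) {
      d <- deserts[as.character(seqnames(deserts)) == nm]
      BiocGenerics::setdiff(IRanges(1, chromLens[nm]), IRanges::ranges(d))
    })
    names(open) <- names(chromLens)
    w <- vapply(open, function(r) sum(BiocGenerics::width(r)), numeric(1))
    if (cellType == "sperm")
      w[names(w) %in% DEFAULT_SEX_CHROMS] <-
        w[names(w) %in% DEFAULT_SEX_CHROMS] * config@xPloidyRatioSperm
    chromIdx <- sample.int(length(w), n, replace = TRUE, prob = w)
    ## lengths: nucleosome-protected (normal truncated at 140 bp, so the
    ## subnucleosomal fraction exactly controls the sub-140 bp mass) plus
    ## subnucleosomal contamination uniform on [100, 140)
    sub <- stats::runif(n) < config@subnucleosomalFraction
    len <- round(stats::rnorm(n, config@fragLenMean, config@fragLenSd))
    while (any(short <- !sub & len < 140))
      len[short] <- round(stats::rnorm(sum(short), config@fragLenMean,
                                       config@fragLenSd))
    len[sub] <- floor(stats::runif(sum(sub), 100, 140))
    ## midpoints uniform over the open (non-desert) part of the chromosome
    mid <- numeric(n)
    for (ci in unique(chromIdx)) {
      r <- open[[ci]]
      widths <- BiocGenerics::width(r)
      cum <- cumsum(widths)
      base <- c(0, cum[-length(cum)])
      sel <- which(chromIdx == ci)
      u <- stats::runif(length(sel), 0, cum[length(cum)])
      ri <- pmin(findInterval(u, base), length(widths))
      mid[sel] <- BiocGenerics::start(r)[ri] + (u - base[ri])
    }
    ## keep the drawn length exactly: shift fragments inward at chromosome
    ## ends instead of clipping them short
    cl <- chromLens[names(chromLens)[chromIdx]]
    start1 <- pmin(pmax(1, round(mid - len / 2)), pmax(1, cl - len + 1))
    end1 <- start1 + len - 1
    frags <- GRanges(names(chromLens)[chromIdx], IRanges(start1, end1),
                     seqlengths = GenomeInfoDb::seqlengths(genes))
    sort(frags)
  })
}
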