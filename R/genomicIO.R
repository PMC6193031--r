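## genomic_io: readers/writers for BED3/BED6, bedGraph, count TSVs and gene
## lists. All genomic coordinates are 0-based half-open on disk (BED
## convention) and 1-based closed GRanges in memory; the conversion happens
## only here. Validation is record-level with line numbers, which is why
## these are parsed with read.table-style code rather than rtracklayer.

## Read a whitespace/tab table skipping blank and '#' lines, keeping the
## original line number of every record.
.readRecords <- function(path, nFields, what) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines) & !grepl("^(track|browser)\\b", lines))
  if (!length(keep))
    return(list(fields = matrix(character(0), 0, nFields), lineno = integer(0)))
  parts <- strsplit(trimws(lines[keep]), "[\t ]+")
  bad <- which(lengths(parts) < nFields)
  if (length(bad))
    stop(sprintf("%s: line %d has %d field(s); %d required",
                 what, keep[bad[1]], lengths(parts)[bad[1]], nFields))
  fields <- t(vapply(parts, function(p) p[seq_len(nFields)], character(nFields)))
  list(fields = matrix(fields, ncol = nFields), lineno = keep)
}

.asCoord <- function(x, what, lineno) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | v != floor(v) | v < 0)
  if (length(bad))
    stop(sprintf("%s: malformed coordinate '%s' at line %d",
                 what, x[bad[1]], lineno[bad[1]]))
  v
}

#' Read a gene annotation (BED6) with optional transcript lengths
#'
#' Reads a BED6-style annotation (0-based, half-open) into a `GRanges` with
#' metadata columns `gene_id`, `transcript_length` (exonic bp of the longest
#' isoform) and `is_autosomal`. Transcript lengths come from an optional
#' two-column table (`gene_id<TAB>length`); genes without an entry fall back
#' to their genomic span length with one warning listing how many fell back.
#'
#' @param path BED6 file (chrom, start, end, name, score, strand).
#' @param lengthTable optional path to a gene_id/length TSV (no header
#'   required; a header line with non-numeric length is skipped).
#' @param sexChroms chromosome names flagged non-autosomal.
#' @return `GRanges` with `gene_id`, `transcript_length`, `is_autosomal`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chrI\t100\t200\tgeneA\t0\t+", bed)
#' genes <- readGeneAnnotation(bed)
#' @export
readGeneAnnotation <- function(path, lengthTable = NULL,
                               sexChroms = DEFAULT_SEX_CHROMS) {
  rec <- .readRecords(path, 6L, "gene annotation")
  f <- rec$fields
  start0 <- .asCoord(f[, 2], "gene annotation", rec$lineno)
  end0 <- .asCoord(f[, 3], "gene annotation", rec$lineno)
  bad <- which(start0 >= end0)
  if (length(bad))
    stop(sprintf("gene annotation: start >= end at line %d (%s)",
                 rec$lineno[bad[1]], f[bad[1], 4]))
  ids <- f[, 4]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("gene annotation: duplicate gene_id '%s'", dup[1]))
  strand <- f[, 6]
  if (!all(strand %in% c("+", "-")))
    stop("gene annotation: strand must be '+' or '-'")
  span <- end0 - start0
  tlen <- span
  if (!is.null(lengthTable)) {
    lt <- utils::read.table(lengthTable, sep = "\t", header = FALSE,
                            col.names = c("gene_id", "length"),
                            colClasses = c("character", "character"))
    lt$length <- suppressWarnings(as.numeric(lt$length))
    lt <- lt[!is.na(lt$length), , drop = FALSE]
    m <- match(ids, lt$gene_id)
    have <- !is.na(m)
    tlen[have] <- lt$length[m[have]]
    if (any(!have))
      warning(sprintf("%d gene(s) missing from length table; using span length",
                      sum(!have)))
  }
  if (any(tlen < 1)) stop("transcript lengths must be >= 1")
  gr <- GRanges(f[, 1], IRanges(start0 + 1, end0), strand = strand)
  gr$gene_id <- ids
  gr$transcript_length <- as.numeric(tlen)
  gr$is_autosomal <- !(f[, 1] %in% sexChroms)
  names(gr) <- ids
  gr
}

#' Read a bedGraph coverage file
#'
#' 0-based half-open, 4 columns, no track header required. Overlapping
#' intervals are an error naming the first overlap; negative values are an
#' error. Book-ended intervals with equal value are merged (canonical form).
#'
#' @param path bedGraph file.
#' @param sexChroms chromosome names classified as sex chromosomes.
#' @return A [CoverageTrack-class] with `scaleState = "raw"`.
#' @export
readBedGraph <- function(path, sexChroms = DEFAULT_SEX_CHROMS) {
  rec <- .readRecords(path, 4L, "bedGraph")
  f <- rec$fields
  if (!nrow(f)) {
    empty <- GRanges()
    empty$score <- numeric(0)
    return(CoverageTrack(empty, sexChroms = sexChroms))
  }
  start0 <- .asCoord(f[, 2], "bedGraph", rec$lineno)
  end0 <- .asCoord(f[, 3], "bedGraph", rec$lineno)
  bad <- which(start0 >= end0)
  if (length(bad))
    stop(sprintf("bedGraph: start >= end at line %d", rec$lineno[bad[1]]))
  val <- suppressWarnings(as.numeric(f[, 4]))
  if (anyNA(val))
    stop(sprintf("bedGraph: non-numeric value at line %d",
                 rec$lineno[which(is.na(val))[1]]))
  neg <- which(val < 0)
  if (length(neg))
    stop(sprintf("bedGraph: negative value %g at line %d",
                 val[neg[1]], rec$lineno[neg[1]]))
  gr <- GRanges(f[, 1], IRanges(start0 + 1, end0), score = val)
  ord <- GenomicRanges::order(gr)
  grs <- gr[ord]
  sameChrom <- as.character(seqnames(grs))[-1L] ==
    as.character(seqnames(grs))[-length(grs)]
  ovl <- which(sameChrom &
                 BiocGenerics::start(grs)[-1L] <= BiocGenerics::end(grs)[-length(grs)])
  if (length(ovl)) {
    i <- ovl[1]
    stop(sprintf("bedGraph: overlapping intervals %s:[%d,%d) and %s:[%d,%d)",
                 as.character(seqnames(grs))[i],
                 BiocGenerics::start(grs)[i] - 1L, BiocGenerics::end(grs)[i],
                 as.character(seqnames(grs))[i + 1],
                 BiocGenerics::start(grs)[i + 1] - 1L, BiocGenerics::end(grs)[i + 1]))
  }
  CoverageTrack(grs, scaleState = "raw", sexChroms = sexChroms)
}

#' Write a CoverageTrack as bedGraph
#'
#' Full-precision values so that `readBedGraph(writeBedGraph(x)) == x`.
#'
#' @param track a [CoverageTrack-class].
#' @param path output file.
#' @export
writeBedGraph <- function(track, path) {
  gr <- trackRanges(track)
  lines <- sprintf("%s\t%d\t%d\t%s", as.character(seqnames(gr)),
                   BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr),
                   formatC(gr$score, digits = 17, format = "g"))
  writeLines(lines, path)
  invisible(path)
}

#' Read sequenced fragments (BED3)
#'
#' @param path BED3 file of fragment intervals (0-based half-open).
#' @return `GRanges` of fragments; width is the fragment length.
#' @export
readFragments <- function(path) {
  rec <- .readRecords(path, 3L, "fragments")
  f <- rec$fields
  if (!nrow(f)) return(GRanges())
  start0 <- .asCoord(f[, 2], "fragments", rec$lineno)
  end0 <- .asCoord(f[, 3], "fragments", rec$lineno)
  bad <- which(start0 >= end0)
  if (length(bad))
    stop(sprintf("fragments: start >= end at line %d", rec$lineno[bad[1]]))
  GRanges(f[, 1], IRanges(start0 + 1, end0))
}

#' Write fragments as BED3
#' @param frags `GRanges` of fragments.
#' @param path output file.
#' @export
writeFragments <- function(frags, path) {
  lines <- sprintf("%s\t%d\t%d", as.character(seqnames(frags)),
                   BiocGenerics::start(frags) - 1L, BiocGenerics::end(frags))
  writeLines(lines, path)
  invisible(path)
}

#' Read a count table with a sample-metadata sidecar
#'
#' Counts are a TSV of genes x samples (header row, first column gene ids),
#' non-negative integers. Metadata is a JSON object
#' `{"samples": {name: {germline_type, genotype, replicate}}}` covering
#' exactly the samples in the table.
#'
#' @param path counts TSV.
#' @param metadataPath JSON sidecar.
#' @return An [ExpressionTable-class].
#' @export
readCounts <- function(path, metadataPath) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           row.names = 1)
  mat <- as.matrix(tab)
  if (!is.numeric(mat)) stop("counts: non-numeric entries")
  if (any(mat < 0)) stop("counts: negative entries")
  if (any(mat != round(mat))) stop("counts: non-integer entries")
  meta <- jsonlite::read_json(metadataPath)
  samples <- meta$samples
  unknown <- setdiff(names(samples), colnames(mat))
  if (length(unknown))
    stop(sprintf("metadata sample(s) not in count table: %s",
                 paste(unknown, collapse = ", ")))
  missing <- setdiff(colnames(mat), names(samples))
  if (length(missing))
    stop(sprintf("count-table sample(s) missing from metadata: %s",
                 paste(missing, collapse = ", ")))
  si <- do.call(rbind, lapply(colnames(mat), function(s) {
    m <- samples[[s]]
    data.frame(germline_type = m$germline_type, genotype = m$genotype,
               replicate = as.integer(m$replicate))
  }))
  rownames(si) <- colnames(mat)
  ExpressionTable(mat, si)
}

#' Write an ExpressionTable's counts and metadata
#'
#' Round-trips losslessly with [readCounts()].
#'
#' @param expr an [ExpressionTable-class].
#' @param path counts TSV output path.
#' @param metadataPath JSON sidecar output path.
#' @export
writeCounts <- function(expr, path, metadataPath) {
  cnt <- SummarizedExperiment::assay(expr, "counts")
  df <- data.frame(gene = rownames(cnt), cnt, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- SummarizedExperiment::colData(expr)
  samples <- lapply(seq_len(nrow(cd)), function(i)
    list(germline_type = cd$germline_type[i], genotype = cd$genotype[i],
         replicate = cd$replicate[i]))
  names(samples) <- rownames(cd)
  jsonlite::write_json(list(samples = samples), metadataPath, auto_unbox = TRUE)
  invisible(path)
}

#' Read a plain-text gene list
#'
#' One id per line; '#' lines are comments. A leading `# name:` /
#' `# provenance:` comment pair written by [writeGeneList()] is recovered.
#'
#' @param path input file.
#' @param name set label (overridden by a `# name:` header if present).
#' @return A [GeneList-class].
#' @export
readGeneList <- function(path, name = basename(path)) {
  lines <- readLines(path)
  prov <- "file"
  nm <- name
  hdr <- grep("^#", lines, value = TRUE)
  nmLine <- grep("^# name: ", hdr, value = TRUE)
  if (length(nmLine)) nm <- sub("^# name: ", "", nmLine[1])
  pvLine <- grep("^# provenance: ", hdr, value = TRUE)
  if (length(pvLine)) prov <- sub("^# provenance: ", "", pvLine[1])
  ids <- trimws(lines[!grepl("^\\s*(#|$)", lines)])
  GeneList(ids, name = nm, provenance = prov)
}

#' Write a gene list as plain text
#' @param geneList a [GeneList-class].
#' @param path output file.
#' @export
writeGeneList <- function(geneList, path) {
  writeLines(c(sprintf("# name: %s", geneList@name),
               sprintf("# provenance: %s", geneList@provenance),
               geneList@ids), path)
  invisible(path)
}

#' Write a data.frame or MarkSignalTable as TSV
#'
#' Tab-separated with a header row and '.' for missing values.
#'
#' @param x data.frame, matrix, or [MarkSignalTable-class].
#' @param path output file.
#' @export
writeTSV <- function(x, path) {
  if (is(x, "MarkSignalTable"))
    x <- data.frame(gene = geneIds(x), signalMatrix(x), check.names = FALSE)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}
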