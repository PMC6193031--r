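#' Accessors for multiMark classes
#'
#' Accessor generics: use these rather than reaching into slots.
#'
#' @param x,object a multiMark object.
#' @param ... passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("trackRanges", function(x) standardGeneric("trackRanges"))

#' @rdname accessors
#' @export
setMethod("trackRanges", "CoverageTrack", function(x) x@ranges)

#' @rdname accessors
#' @export
setGeneric("scaleState", function(x) standardGeneric("scaleState"))

#' @rdname accessors
#' @export
setMethod("scaleState", "CoverageTrack", function(x) x@scaleState)

#' @rdname accessors
#' @export
setGeneric("sexChroms", function(x) standardGeneric("sexChroms"))

#' @rdname accessors
#' @export
setMethod("sexChroms", "CoverageTrack", function(x) x@sexChroms)

#' Total autosomal signal of a track
#'
#' Sum over autosomal intervals of value x interval width (in bp). Sex
#' chromosomes (per [sexChroms()]) are excluded; this is the quantity the
#' autosome-referenced scaling normalizes to its target.
#'
#' @param x a [CoverageTrack-class].
#' @return numeric scalar.
#' @export
setGeneric("autosomalTotal", function(x) standardGeneric("autosomalTotal"))

#' @rdname autosomalTotal
#' @export
setMethod("autosomalTotal", "CoverageTrack", function(x) {
  gr <- x@ranges
  auto <- !(as.character(seqnames(gr)) %in% x@sexChroms)
  sum(as.numeric(BiocGenerics::width(gr[auto])) * gr$score[auto])
})

#' @rdname accessors
#' @export
setGeneric("signalStage", function(x) standardGeneric("signalStage"))

#' @rdname accessors
#' @export
setMethod("signalStage", "MarkSignalTable", function(x) x@stage)

#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @rdname accessors
#' @export
setMethod("signalMatrix", "MarkSignalTable", function(x) x@signal)

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setMethod("geneIds", "MarkSignalTable", function(x) rownames(x@signal))

#' @rdname accessors
#' @export
setMethod("geneIds", "GeneList", function(x) x@ids)

#' @rdname accessors
#' @export
setMethod("geneIds", "QuadrantCall", function(x) x@gene)

#' @rdname accessors
#' @export
setMethod("geneIds", "DEResult", function(x) x@table$gene)

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setMethod("provenance", "MarkSignalTable", function(x) x@provenance)

#' @rdname accessors
#' @export
setMethod("provenance", "GeneList", function(x) x@provenance)

#' @rdname accessors
#' @export
setMethod("provenance", "DEResult", function(x) x@provenance)

#' @rdname accessors
#' @export
setGeneric("deTable", function(x) standardGeneric("deTable"))

#' @rdname accessors
#' @export
setMethod("deTable", "DEResult", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("quadrantLabels", function(x) standardGeneric("quadrantLabels"))

#' @rdname accessors
#' @export
setMethod("quadrantLabels", "QuadrantCall", function(x)
  stats::setNames(x@label, x@gene))

#' @rdname accessors
#' @export
setGeneric("isMultivalent", function(x) standardGeneric("isMultivalent"))

#' @rdname accessors
#' @export
setMethod("isMultivalent", "QuadrantCall", function(x)
  stats::setNames(x@multivalent, x@gene))

#' @rdname accessors
#' @export
setGeneric("occupancyWindows", function(x) standardGeneric("occupancyWindows"))

#' @rdname accessors
#' @export
setMethod("occupancyWindows", "WindowOccupancyTable", function(x) x@windows)

#' @rdname accessors
#' @export
setGeneric("occupancyMatrix", function(x) standardGeneric("occupancyMatrix"))

#' @rdname accessors
#' @export
setMethod("occupancyMatrix", "WindowOccupancyTable", function(x) x@coverage)

#' @rdname accessors
#' @export
setGeneric("rawFragmentCounts", function(x) standardGeneric("rawFragmentCounts"))

#' @rdname accessors
#' @export
setMethod("rawFragmentCounts", "WindowOccupancyTable", function(x) x@rawCounts)

#' @rdname accessors
#' @export
setGeneric("excludedWindows", function(x) standardGeneric("excludedWindows"))

#' @rdname accessors
#' @export
setMethod("excludedWindows", "WindowOccupancyTable", function(x) x@excluded)
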