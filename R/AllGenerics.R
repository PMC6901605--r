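#' @include AllClasses.R
NULL

#' Accessors for polyBCR classes
#'
#' @param x A polyBCR object.
#' @param ... Further arguments (unused).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("contigData", function(x, ...) standardGeneric("contigData"))

#' @rdname accessors
#' @export
setMethod("contigData", "ContigTable", function(x, ...) x@contigs)

#' @rdname accessors
#' @export
setGeneric("dialect", function(x) standardGeneric("dialect"))

#' @rdname accessors
#' @export
setMethod("dialect", "ContigTable", function(x) x@dialect)

#' @rdname accessors
#' @export
setGeneric("nDropped", function(x) standardGeneric("nDropped"))

#' @rdname accessors
#' @export
setMethod("nDropped", "ContigTable", function(x) x@nDropped)

#' @rdname accessors
#' @export
setGeneric("barcodes", function(x) standardGeneric("barcodes"))

#' @rdname accessors
#' @export
setMethod("barcodes", "ContigTable", function(x) unique(x@contigs$barcode))

#' @rdname accessors
#' @export
setMethod("barcodes", "CellProfileSet", function(x) x@cells$barcode)

#' @rdname accessors
#' @export
setGeneric("keyMode", function(x) standardGeneric("keyMode"))

#' @rdname accessors
#' @export
setMethod("keyMode", "CellProfileSet", function(x) x@keyMode)

#' @rdname accessors
#' @export
setGeneric("cellData", function(x, ...) standardGeneric("cellData"))

#' @rdname accessors
#' @export
setMethod("cellData", "CellProfileSet", function(x, ...) x@cells)

#' Per-locus pattern and V-gene sets
#'
#' @param x A [CellProfileSet-class].
#' @param locus One of \code{"IGH"}, \code{"IGK"}, \code{"IGL"}.
#' @return A \code{CharacterList} parallel to [barcodes()], one sorted set
#'   per cell.
#' @export
setGeneric("patternsByLocus", function(x, locus) standardGeneric("patternsByLocus"))

#' @rdname patternsByLocus
#' @export
setMethod("patternsByLocus", "CellProfileSet", function(x, locus) {
  locus <- match.arg(locus, .LOCI)
  stats::setNames(x@cells[[paste0("patterns_", locus)]], x@cells$barcode)
})

#' @rdname patternsByLocus
#' @export
setGeneric("vGenesByLocus", function(x, locus) standardGeneric("vGenesByLocus"))

#' @rdname patternsByLocus
#' @export
setMethod("vGenesByLocus", "CellProfileSet", function(x, locus) {
  locus <- match.arg(locus, .LOCI)
  stats::setNames(x@cells[[paste0("vgenes_", locus)]], x@cells$barcode)
})

#' @rdname accessors
#' @export
setGeneric("cClasses", function(x) standardGeneric("cClasses"))

#' @rdname accessors
#' @export
setMethod("cClasses", "CellProfileSet", function(x)
  stats::setNames(x@cells$c_classes, x@cells$barcode))

#' @rdname accessors
#' @export
setGeneric("classPatterns", function(x) standardGeneric("classPatterns"))

#' @rdname accessors
#' @export
setMethod("classPatterns", "CellProfileSet", function(x) x@classPatterns)

#' @rdname accessors
#' @export
setGeneric("subsets", function(x) standardGeneric("subsets"))

#' @rdname accessors
#' @export
setMethod("subsets", "CellProfileSet", function(x)
  stats::setNames(x@cells$subset, x@cells$barcode))

#' @rdname accessors
#' @param value Replacement value.
#' @export
setGeneric("subsets<-", function(x, value) standardGeneric("subsets<-"))

#' @rdname accessors
#' @export
setMethod("subsets<-", "CellProfileSet", function(x, value) {
  stopifnot(length(value) == nrow(x@cells))
  x@cells$subset <- unname(value)
  validObject(x)
  x
})

#' @rdname accessors
#' @export
setGeneric("segmentInfo", function(x) standardGeneric("segmentInfo"))

#' @rdname accessors
#' @export
setMethod("segmentInfo", "GermlineRegistry", function(x) x@info)

#' @rdname accessors
#' @export
setGeneric("segmentSequences", function(x) standardGeneric("segmentSequences"))

#' @rdname accessors
#' @export
setMethod("segmentSequences", "GermlineRegistry", function(x) x@sequences)

#' Segment names of one pool of a registry
#'
#' @param x A [GermlineRegistry-class].
#' @param locus,type Pool selector, e.g. \code{"IGH"}, \code{"V"}.
#' @return Character vector of segment names.
#' @export
segmentNames <- function(x, locus, type) {
  info <- x@info
  info$name[info$locus == locus & info$type == type]
}

#' @rdname accessors
#' @export
setMethod("length", "ContigTable", function(x) nrow(x@contigs))

#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname accessors
#' @export
setMethod("nCells", "CellProfileSet", function(x) nrow(x@cells))
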