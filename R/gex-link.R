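#' @include AllClasses.R
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#' @importFrom S4Vectors DataFrame
NULL

#' Barcode overlap between V(D)J and gene-expression libraries
#'
#' Exact-string intersection of the cell barcodes detected by the V(D)J
#' enrichment library and the 5' gene-expression (GEX) library of the same
#' sample. The overlap fraction is reported relative to the V(D)J set:
#' the fraction of V(D)J-detected cells that were also captured by GEX.
#'
#' @param vdjBarcodes Character vector (or set) of V(D)J barcodes; must be
#'   non-empty.
#' @param gexBarcodes Character vector of GEX barcodes.
#' @return An [OverlapStats-class].
#' @examples
#' barcodeOverlap(c("A-1", "B-1", "C-1"), c("B-1", "C-1", "D-1"))
#' @export
barcodeOverlap <- function(vdjBarcodes, gexBarcodes) {
  vdj <- unique(as.character(vdjBarcodes))
  gex <- unique(as.character(gexBarcodes))
  if (!length(vdj)) stop("V(D)J barcode set must be non-empty")
  nOv <- length(intersect(vdj, gex))
  new("OverlapStats", nVdj = length(vdj), nGex = length(gex),
      nOverlap = nOv, fractionOfVdj = nOv / length(vdj))
}

.markerValues <- function(x, gene) {
  if (is(x, "SummarizedExperiment")) {
    if (!gene %in% rownames(x))
      stop("required marker gene missing from expression matrix: ", gene)
    as.numeric(assay(x)[gene, ])
  } else {
    if (!gene %in% rownames(x))
      stop("required marker gene missing from expression matrix: ", gene)
    as.numeric(x[gene, ])
  }
}

#' Classify B-cell subsets from marker expression
#'
#' Assigns each barcode exactly one of \code{plasma}, \code{naive},
#' \code{memory}, or \code{unassigned} by explicit marker rules evaluated
#' in priority order: plasma first (CD19+ with CD38 at or above the high
#' cutoff, the "CD38+++" population), then naive (CD19+ CD27- IGHM+
#' IGHD+), then memory (CD19+ CD27+). This rule-based classifier replaces
#' cluster-annotation pipelines and consumes any normalized expression
#' matrix.
#'
#' When no explicit CD38-high cutoff is configured, the cutoff defaults to
#' the \code{cd38Quantile} percentile (default 90th) of CD38 across CD19+
#' cells. Note that a percentile rule necessarily marks a fixed share of
#' cells as CD38-high, so an explicit cutoff is preferable whenever the
#' expected plasma fraction is far from \code{1 - cd38Quantile}.
#'
#' @param x A \code{SummarizedExperiment} (genes x cells, first assay) or
#'   a numeric matrix with gene rownames and barcode colnames, holding
#'   normalized expression. Must contain CD19, CD27, CD38, IGHM, IGHD
#'   (and CD10 when \code{useCd10}).
#' @param rules A [MarkerRuleSet-class]; see [markerRules()].
#' @return Named character vector, one label per barcode.
#' @export
classifySubsets <- function(x, rules = markerRules()) {
  stopifnot(is(rules, "MarkerRuleSet"))
  bcs <- colnames(x)
  if (is.null(bcs) || anyDuplicated(bcs))
    stop("expression matrix must have unique barcode column names")
  cd19 <- .markerValues(x, "CD19")
  cd27 <- .markerValues(x, "CD27")
  cd38 <- .markerValues(x, "CD38")
  ighm <- .markerValues(x, "IGHM")
  ighd <- .markerValues(x, "IGHD")
  pos <- rules@positiveCutoff
  cd19pos <- cd19 > pos
  cutoff <- rules@cd38HighCutoff
  if (is.na(cutoff)) {
    if (!any(cd19pos)) stop("no CD19-positive cells to anchor the CD38 cutoff")
    cutoff <- stats::quantile(cd38[cd19pos], rules@cd38Quantile, names = FALSE)
  }
  naiveRule <- cd19pos & cd27 <= pos & ighm > pos & ighd > pos
  if (rules@useCd10) {
    cd10 <- .markerValues(x, "CD10")
    naiveRule <- naiveRule & cd10 <= pos
  }
  out <- rep("unassigned", length(bcs))
  memoryRule <- cd19pos & cd27 > pos
  out[memoryRule] <- "memory"
  out[naiveRule] <- "naive"
  out[cd19pos & cd38 >= cutoff] <- "plasma"
  stats::setNames(out, bcs)
}

#' Attach subset labels to cell profiles
#'
#' Left-join on the profile (V(D)J) side: profiles whose barcode appears
#' in the label map get that subset; unmatched profiles keep
#' \code{"unassigned"}. Duplicate barcodes in the label map are rejected.
#'
#' @param profiles A [CellProfileSet-class].
#' @param labels Named character vector (barcode -> subset), e.g. from
#'   [classifySubsets()].
#' @return The profile set with its \code{subset} field filled in.
#' @export
joinProfiles <- function(profiles, labels) {
  stopifnot(is(profiles, "CellProfileSet"))
  if (is.null(names(labels))) stop("labels must be named by barcode")
  if (anyDuplicated(names(labels)))
    stop("duplicate barcode(s) in label map: ",
         paste(unique(names(labels)[duplicated(names(labels))]), collapse = ", "))
  bad <- setdiff(unique(labels), .SUBSETS)
  if (length(bad))
    stop("unknown subset label(s): ", paste(bad, collapse = ", "))
  idx <- match(profiles@cells$barcode, names(labels))
  hit <- !is.na(idx)
  profiles@cells$subset[hit] <- unname(labels[idx[hit]])
  validObject(profiles)
  profiles
}

#' Read a normalized expression matrix
#'
#' Accepts either a 10x-style MTX directory (\code{matrix.mtx} +
#' \code{features.tsv} + \code{barcodes.tsv}, genes x cells) or a dense
#' TSV with cells in rows (first column barcode) and genes in columns.
#' Either way the result is genes x cells.
#'
#' @param path Directory (MTX) or file (dense TSV).
#' @return A \code{SummarizedExperiment} with one assay
#'   \code{"logcounts"}.
#' @export
readExpressionMatrix <- function(path) {
  if (dir.exists(path)) {
    m <- as.matrix(Matrix::readMM(file.path(path, "matrix.mtx")))
    feats <- utils::read.delim(file.path(path, "features.tsv"),
                               header = FALSE, colClasses = "character")
    bcs <- utils::read.delim(file.path(path, "barcodes.tsv"),
                             header = FALSE, colClasses = "character")
    rownames(m) <- feats[[1]]
    colnames(m) <- bcs[[1]]
  } else {
    d <- utils::read.delim(path, check.names = FALSE)
    m <- t(as.matrix(d[, -1, drop = FALSE]))
    colnames(m) <- d[[1]]
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop("duplicate gene or barcode names in expression matrix")
  if (any(!is.finite(m))) stop("non-finite expression values")
  SummarizedExperiment(assays = list(logcounts = m),
                       colData = DataFrame(barcode = colnames(m)))
}

#' Write an expression matrix as a 10x-style MTX directory
#'
#' @param x SummarizedExperiment (genes x cells) or matrix.
#' @param dir Output directory (created if needed).
#' @return Invisibly, \code{dir}.
#' @export
writeExpressionMatrix <- function(x, dir) {
  m <- if (is(x, "SummarizedExperiment")) assay(x) else x
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(as.matrix(m), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(rownames(m), rownames(m), "Gene Expression"),
                     file.path(dir, "features.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(colnames(m), file.path(dir, "barcodes.tsv"),
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(dir)
}
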