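#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

# Internal schema shared by both dialects: one row per assembled contig.
.CONTIG_COLUMNS <- c(
  "barcode", "contig_id", "locus", "v_call", "d_call", "j_call", "c_call",
  "cdr3_aa", "cdr3_nt", "productive", "full_length", "high_confidence",
  "is_cell", "umis", "reads"
)

.LOCI <- c("IGH", "IGK", "IGL")
.IGH_CLASSES <- c("IGHM", "IGHD", "IGHG", "IGHA", "IGHE")
.SUBSETS <- c("naive", "memory", "plasma", "unassigned")
.KEY_MODES <- c("gene_only", "gene_cdr3nt", "gene_cdr3aa")

#' ContigTable: normalized single-cell V(D)J contig annotations
#'
#' One row per assembled contig, normalized from either the 10x Genomics
#' \code{filtered_contig_annotations.csv} dialect or the AIRR rearrangement
#' TSV dialect. Gene calls are gene-level (first listed gene, allele suffix
#' stripped); \code{cdr3_nt} excludes the conserved flanking codons.
#'
#' @slot contigs A \code{DataFrame} with the internal schema columns
#'   \code{barcode, contig_id, locus, v_call, d_call, j_call, c_call,
#'   cdr3_aa, cdr3_nt, productive, full_length, high_confidence, is_cell,
#'   umis, reads}.
#' @slot dialect Source dialect, \code{"tenx_csv"} or \code{"airr_tsv"}.
#' @slot source Free-text provenance label.
#' @slot nDropped Number of input rows dropped during normalization
#'   (e.g. non-BCR chains), so that rows in = contigs out + dropped.
#'
#' @seealso [readContigTable()], [writeContigTable()], [qcFilter()]
#' @export
setClass("ContigTable",
  slots = c(
    contigs = "DataFrame",
    dialect = "character",
    source = "character",
    nDropped = "integer"
  )
)

setValidity("ContigTable", function(object) {
  df <- object@contigs
  msg <- character()
  missing <- setdiff(.CONTIG_COLUMNS, colnames(df))
  if (length(missing))
    return(paste("missing contig columns:", paste(missing, collapse = ", ")))
  if (!object@dialect %in% c("tenx_csv", "airr_tsv"))
    msg <- c(msg, "dialect must be 'tenx_csv' or 'airr_tsv'")
  if (nrow(df)) {
    if (anyNA(df$barcode) || any(!nzchar(df$barcode)))
      msg <- c(msg, "all barcodes must be non-empty")
    if (anyDuplicated(df$contig_id))
      msg <- c(msg, "contig_id must be unique within a table")
    bad <- !df$locus %in% .LOCI
    if (any(bad))
      msg <- c(msg, paste("unknown locus:", paste(unique(df$locus[bad]), collapse = ", ")))
    if (any(df$locus %in% c("IGK", "IGL") & !is.na(df$d_call)))
      msg <- c(msg, "d_call must be NA for light-chain loci")
    if (any(!is.na(df$umis) & df$umis < 0))
      msg <- c(msg, "umis must be non-negative")
    both <- !is.na(df$cdr3_nt) & !is.na(df$cdr3_aa)
    if (any(both & nchar(df$cdr3_nt) %% 3L != 0L))
      msg <- c(msg, "cdr3_nt length must be divisible by 3 when cdr3_aa is present")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ContigTable from a data.frame in the internal schema
#'
#' @param contigs data.frame or DataFrame with the internal schema columns.
#' @param dialect dialect label recorded for round-trips.
#' @param source provenance label.
#' @param nDropped rows dropped during normalization.
#' @return A [ContigTable-class] object.
#' @export
ContigTable <- function(contigs, dialect = "tenx_csv", source = "",
                        nDropped = 0L) {
  df <- DataFrame(contigs)
  for (col in c("barcode", "contig_id", "locus", "v_call", "d_call",
                "j_call", "c_call", "cdr3_aa", "cdr3_nt"))
    df[[col]] <- as.character(df[[col]])
  for (col in c("productive", "full_length", "high_confidence", "is_cell"))
    df[[col]] <- as.logical(df[[col]])
  for (col in c("umis", "reads")) df[[col]] <- as.integer(df[[col]])
  df <- df[, .CONTIG_COLUMNS]
  rownames(df) <- NULL
  new("ContigTable", contigs = df, dialect = dialect, source = source,
      nDropped = as.integer(nDropped))
}

#' CellProfileSet: per-cell V(D)J pattern profiles
#'
#' Aggregates a QC-filtered [ContigTable-class] by cell barcode into the
#' per-cell quantities the analysis operates on: the set of distinct
#' recombination patterns per locus, the set of V genes per locus, the set
#' of heavy-chain constant-region classes, and per-class pattern sets.
#'
#' A "recombination pattern" is the identity key of one rearrangement. The
#' active key mode decides what makes two patterns distinct: germline gene
#' calls only (\code{gene_only}), gene calls plus CDR3 nucleotide sequence
#' (\code{gene_cdr3nt}, the default), or gene calls plus CDR3 amino-acid
#' sequence (\code{gene_cdr3aa}). Pattern keys are encoded as
#' \code{"locus|v|d|j|cdr3"} strings, sorted lexicographically.
#'
#' @slot cells A \code{DataFrame}, one row per barcode, with
#'   \code{CharacterList} columns \code{patterns_IGH/IGK/IGL},
#'   \code{vgenes_IGH/IGK/IGL}, \code{c_classes}, plus \code{subset} and any
#'   user grouping columns (e.g. donor).
#' @slot classPatterns Long-format \code{DataFrame} (\code{barcode},
#'   \code{c_class}, \code{pattern}) assigning each classed IGH pattern to
#'   its constant-region class.
#' @slot keyMode The active pattern key mode.
#'
#' @seealso [buildCellProfiles()], [multiplicityCategory()],
#'   [lightChainUsage()], [summarizeCohort()]
#' @export
setClass("CellProfileSet",
  slots = c(
    cells = "DataFrame",
    classPatterns = "DataFrame",
    keyMode = "character"
  )
)

setValidity("CellProfileSet", function(object) {
  msg <- character()
  need <- c("barcode", paste0("patterns_", .LOCI), paste0("vgenes_", .LOCI),
            "c_classes", "subset")
  missing <- setdiff(need, colnames(object@cells))
  if (length(missing))
    return(paste("missing cell columns:", paste(missing, collapse = ", ")))
  if (!object@keyMode %in% .KEY_MODES)
    msg <- c(msg, paste("keyMode must be one of:", paste(.KEY_MODES, collapse = ", ")))
  if (anyDuplicated(object@cells$barcode))
    msg <- c(msg, "one profile per barcode required")
  cls <- unlist(object@cells$c_classes)
  if (length(cls) && !all(cls %in% .IGH_CLASSES))
    msg <- c(msg, "c_classes must be within IGHM/IGHD/IGHG/IGHA/IGHE")
  if (!all(object@cells$subset %in% .SUBSETS))
    msg <- c(msg, "subset labels must be naive/memory/plasma/unassigned")
  if (length(msg)) msg else TRUE
})

#' GermlineRegistry: named V/D/J germline segment pools
#'
#' Nucleotide sequences for the V, D, and J segment pools of each locus,
#' with IMGT-style names (synthetic registries use names like
#' \code{IGHV1-S1}). The D pool is empty for the light-chain loci.
#'
#' @slot sequences \code{DNAStringSet} of all segments, named.
#' @slot info \code{DataFrame} with columns \code{name}, \code{locus}
#'   (IGH/IGK/IGL) and \code{type} (V/D/J), parallel to \code{sequences}.
#'
#' @seealso [buildRegistry()], [readRegistryFasta()], [assignGermline()]
#' @export
setClass("GermlineRegistry",
  slots = c(sequences = "DNAStringSet", info = "DataFrame")
)

setValidity("GermlineRegistry", function(object) {
  msg <- character()
  info <- object@info
  if (!all(c("name", "locus", "type") %in% colnames(info)))
    return("info needs columns name, locus, type")
  if (length(object@sequences) != nrow(info))
    return("sequences and info must be parallel")
  if (anyDuplicated(info$name)) msg <- c(msg, "segment names must be unique")
  if (!all(info$locus %in% .LOCI)) msg <- c(msg, "unknown locus in registry")
  if (!all(info$type %in% c("V", "D", "J"))) msg <- c(msg, "type must be V/D/J")
  if (any(info$type == "D" & info$locus != "IGH"))
    msg <- c(msg, "D pool must be empty for light-chain loci")
  if (length(object@sequences) && any(Biostrings::width(object@sequences) == 0))
    msg <- c(msg, "zero-length segment sequence")
  if (length(msg)) msg else TRUE
})

#' OverlapStats: barcode overlap between V(D)J and GEX libraries
#'
#' @slot nVdj,nGex,nOverlap Barcode counts.
#' @slot fractionOfVdj \code{nOverlap / nVdj}, the fraction of V(D)J cells
#'   also detected by the 5' gene-expression library.
#' @seealso [barcodeOverlap()]
#' @export
setClass("OverlapStats",
  slots = c(nVdj = "integer", nGex = "integer", nOverlap = "integer",
            fractionOfVdj = "numeric")
)

setValidity("OverlapStats", function(object) {
  if (object@nOverlap > min(object@nVdj, object@nGex))
    return("overlap cannot exceed either set size")
  TRUE
})

#' MarkerRuleSet: marker-based B-cell subset classification rules
#'
#' Explicit rules over normalized marker expression, replacing
#' cluster-annotation pipelines: plasma = CD19+ and CD38 at or above the
#' high cutoff; naive = CD19+ CD27- IGHM+ IGHD+; memory = CD19+ CD27+ and
#' not plasma. Rules are applied in priority order plasma, naive, memory;
#' everything else is unassigned, so each cell gets exactly one label.
#'
#' @slot positiveCutoff A marker is "positive" when its value exceeds this
#'   (default 0, i.e. any detected expression after normalization).
#' @slot cd38HighCutoff Explicit CD38-high threshold; \code{NA} means use the
#'   \code{cd38Quantile} percentile of CD38 across CD19+ cells.
#' @slot cd38Quantile Percentile used when \code{cd38HighCutoff} is NA.
#' @slot useCd10 Include the optional CD10-negative term in the naive rule.
#' @seealso [markerRules()], [classifySubsets()]
#' @export
setClass("MarkerRuleSet",
  slots = c(positiveCutoff = "numeric", cd38HighCutoff = "numeric",
            cd38Quantile = "numeric", useCd10 = "logical")
)

#' @describeIn MarkerRuleSet-class Constructor.
#' @param positiveCutoff,cd38HighCutoff,cd38Quantile,useCd10 see slots.
#' @return A \code{MarkerRuleSet}.
#' @export
markerRules <- function(positiveCutoff = 0, cd38HighCutoff = NA_real_,
                        cd38Quantile = 0.9, useCd10 = FALSE) {
  new("MarkerRuleSet", positiveCutoff = positiveCutoff,
      cd38HighCutoff = as.numeric(cd38HighCutoff),
      cd38Quantile = cd38Quantile, useCd10 = useCd10)
}

setMethod("show", "ContigTable", function(object) {
  cat(sprintf("ContigTable with %d contigs across %d barcodes [%s]\n",
              nrow(object@contigs), length(unique(object@contigs$barcode)),
              object@dialect))
  if (object@nDropped > 0L)
    cat(sprintf("  (%d input rows dropped during normalization)\n",
                object@nDropped))
  loc <- table(factor(object@contigs$locus, levels = .LOCI))
  cat(sprintf("  IGH: %d  IGK: %d  IGL: %d\n", loc["IGH"], loc["IGK"], loc["IGL"]))
})

setMethod("show", "CellProfileSet", function(object) {
  cat(sprintf("CellProfileSet with %d cells (key mode: %s)\n",
              nrow(object@cells), object@keyMode))
  sub <- table(factor(object@cells$subset, levels = .SUBSETS))
  cat("  subsets:", paste(sprintf("%s=%d", names(sub), sub), collapse = " "), "\n")
})

setMethod("show", "GermlineRegistry", function(object) {
  tab <- table(object@info$locus, object@info$type)
  cat("GermlineRegistry:\n")
  print(tab)
})

setMethod("show", "OverlapStats", function(object) {
  cat(sprintf("Barcode overlap: %d / %d V(D)J cells also in GEX (%.2f%%); GEX n = %d\n",
              object@nOverlap, object@nVdj, 100 * object@fractionOfVdj,
              object@nGex))
})
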