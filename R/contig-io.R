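#' @include AllClasses.R utils.R
NULL

.TENX_COLUMNS <- c(
  "barcode", "is_cell", "contig_id", "high_confidence", "length", "chain",
  "v_gene", "d_gene", "j_gene", "c_gene", "full_length", "productive",
  "cdr3", "cdr3_nt", "reads", "umis", "raw_clonotype_id"
)

.AIRR_REQUIRED <- c(
  "cell_id", "locus", "v_call", "d_call", "j_call", "c_call",
  "junction", "junction_aa", "productive"
)

# 10x boolean strings, case-insensitive; the literal "None" means false.
.parseTenxBool <- function(x) {
  low <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[low %in% c("true", "t")] <- TRUE
  out[low %in% c("false", "f", "none", "")] <- FALSE
  out[is.na(x)] <- FALSE
  out
}

.parseAirrBool <- function(x) {
  low <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[low %in% c("t", "true", "1")] <- TRUE
  out[low %in% c("f", "false", "0", "")] <- FALSE
  out[is.na(x)] <- FALSE
  out
}

.noneToNA <- function(x) {
  x <- trimws(x)
  x[is.na(x) | x == "" | tolower(x) == "none"] <- NA_character_
  x
}

#' Read a single-cell V(D)J contig annotation table
#'
#' Reads either the 10x Genomics \code{filtered_contig_annotations.csv}
#' dialect or an AIRR rearrangement TSV and normalizes both into the
#' internal contig schema. Normalization keeps the first listed gene of a
#' multi-allele call with its allele suffix stripped, maps 10x
#' \code{"None"} booleans to \code{FALSE}, and trims the conserved flanking
#' codons from the AIRR \code{junction} so that \code{cdr3_nt} means the
#' same thing in both dialects (the 10x \code{cdr3_nt} is taken as already
#' CDR3). Rows whose chain is not IGH/IGK/IGL (e.g. TCR chains) are dropped
#' with a warning and counted in [nDropped()].
#'
#' @param path Path to the file.
#' @param dialect \code{"tenx"} or \code{"airr"}.
#' @param source Provenance label stored on the table (defaults to the
#'   file name).
#' @return A [ContigTable-class].
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' ct <- ContigTable(data.frame(
#'   barcode = "AAACCTGA-1", contig_id = "AAACCTGA-1_contig_1",
#'   locus = "IGH", v_call = "IGHV1-69", d_call = "IGHD3-10",
#'   j_call = "IGHJ4", c_call = "IGHM", cdr3_aa = "CARDY",
#'   cdr3_nt = "TGTGCGAGAGATTAC", productive = TRUE, full_length = TRUE,
#'   high_confidence = TRUE, is_cell = TRUE, umis = 5L, reads = 100L))
#' writeContigTable(ct, tf, dialect = "tenx")
#' readContigTable(tf, dialect = "tenx")
#' @export
readContigTable <- function(path, dialect = c("tenx", "airr"),
                            source = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tenx") .readTenx(path, source) else .readAirr(path, source)
}

.readTenx <- function(path, source) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = character())
  missing <- setdiff(.TENX_COLUMNS, colnames(raw))
  # length and raw_clonotype_id are carried by Cell Ranger but unused here
  missing <- setdiff(missing, c("length", "raw_clonotype_id"))
  if (length(missing))
    stop("10x contig file is missing required column(s): ",
         paste(missing, collapse = ", "))
  keep <- raw$chain %in% .LOCI
  nDropped <- sum(!keep)
  if (nDropped > 0L)
    warning(sprintf("dropped %d row(s) with non-BCR chain value(s): %s",
                    nDropped,
                    paste(unique(raw$chain[!keep]), collapse = ", ")))
  raw <- raw[keep, , drop = FALSE]
  df <- data.frame(
    barcode = raw$barcode,
    contig_id = raw$contig_id,
    locus = raw$chain,
    v_call = normalizeGeneCall(.noneToNA(raw$v_gene)),
    d_call = normalizeGeneCall(.noneToNA(raw$d_gene)),
    j_call = normalizeGeneCall(.noneToNA(raw$j_gene)),
    c_call = normalizeGeneCall(.noneToNA(raw$c_gene)),
    cdr3_aa = .noneToNA(raw$cdr3),
    cdr3_nt = .noneToNA(raw$cdr3_nt),
    productive = .parseTenxBool(raw$productive),
    full_length = .parseTenxBool(raw$full_length),
    high_confidence = .parseTenxBool(raw$high_confidence),
    is_cell = .parseTenxBool(raw$is_cell),
    umis = suppressWarnings(as.integer(raw$umis)),
    reads = suppressWarnings(as.integer(raw$reads)),
    stringsAsFactors = FALSE
  )
  df$d_call[df$locus != "IGH"] <- NA_character_
  ContigTable(df, dialect = "tenx_csv", source = source, nDropped = nDropped)
}

.readAirr <- function(path, source) {
  raw <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE, na.strings = character())
  missing <- setdiff(.AIRR_REQUIRED, colnames(raw))
  if (length(missing))
    stop("AIRR rearrangement file is missing required column(s): ",
         paste(missing, collapse = ", "))
  keep <- raw$locus %in% .LOCI
  nDropped <- sum(!keep)
  if (nDropped > 0L)
    warning(sprintf("dropped %d row(s) with non-BCR locus value(s): %s",
                    nDropped,
                    paste(unique(raw$locus[!keep]), collapse = ", ")))
  raw <- raw[keep, , drop = FALSE]
  opt <- function(col, default) {
    if (col %in% colnames(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  junction <- .noneToNA(raw$junction)
  junction_aa <- .noneToNA(raw$junction_aa)
  # AIRR junction includes the conserved flanking C and W/F codons;
  # CDR3 = junction minus the first and last codon.
  trimNt <- function(x) ifelse(!is.na(x) & nchar(x) > 6,
                               substr(x, 4, nchar(x) - 3), NA_character_)
  trimAa <- function(x) ifelse(!is.na(x) & nchar(x) > 2,
                               substr(x, 2, nchar(x) - 1), NA_character_)
  df <- data.frame(
    barcode = raw$cell_id,
    contig_id = opt("sequence_id",
                    if (nrow(raw)) paste0("seq", seq_len(nrow(raw))) else character()),
    locus = raw$locus,
    v_call = normalizeGeneCall(.noneToNA(raw$v_call)),
    d_call = normalizeGeneCall(.noneToNA(raw$d_call)),
    j_call = normalizeGeneCall(.noneToNA(raw$j_call)),
    c_call = normalizeGeneCall(.noneToNA(raw$c_call)),
    cdr3_aa = trimAa(junction_aa),
    cdr3_nt = trimNt(junction),
    productive = .parseAirrBool(raw$productive),
    full_length = .parseAirrBool(opt("complete_vdj", "T")),
    high_confidence = .parseAirrBool(opt("high_confidence", "T")),
    is_cell = .parseAirrBool(opt("is_cell", "T")),
    umis = suppressWarnings(as.integer(opt("duplicate_count", NA))),
    reads = suppressWarnings(as.integer(opt("consensus_count", NA))),
    stringsAsFactors = FALSE
  )
  df$d_call[df$locus != "IGH"] <- NA_character_
  ContigTable(df, dialect = "airr_tsv", source = source, nDropped = nDropped)
}

#' Write a contig table in either dialect
#'
#' Writing then re-reading reproduces every normalized field (round-trip
#' identity on the internal schema), whichever dialect is chosen. Null gene
#' calls are written as \code{"None"} in the 10x dialect and as empty
#' strings in AIRR. Because the internal schema stores the CDR3 without the
#' conserved flanks, the AIRR \code{junction} is written with canonical
#' flanking codons (TGT ... TGG) re-attached; re-reading trims them again.
#'
#' @param table A [ContigTable-class].
#' @param path Output file path (UTF-8).
#' @param dialect \code{"tenx"} (CSV) or \code{"airr"} (TSV).
#' @return Invisibly, \code{path}.
#' @export
writeContigTable <- function(table, path, dialect = c("tenx", "airr")) {
  dialect <- match.arg(dialect)
  stopifnot(is(table, "ContigTable"))
  df <- as.data.frame(table@contigs)
  if (dialect == "tenx") {
    toNone <- function(x) ifelse(is.na(x), "None", x)
    toBool <- function(x) ifelse(x, "True", "False")
    out <- data.frame(
      barcode = df$barcode,
      is_cell = toBool(df$is_cell),
      contig_id = df$contig_id,
      high_confidence = toBool(df$high_confidence),
      length = ifelse(is.na(df$cdr3_nt), 0L, nchar(df$cdr3_nt)),
      chain = df$locus,
      v_gene = toNone(df$v_call),
      d_gene = toNone(df$d_call),
      j_gene = toNone(df$j_call),
      c_gene = toNone(df$c_call),
      full_length = toBool(df$full_length),
      productive = toBool(df$productive),
      cdr3 = toNone(df$cdr3_aa),
      cdr3_nt = toNone(df$cdr3_nt),
      reads = df$reads,
      umis = df$umis,
      raw_clonotype_id = rep("None", nrow(df)),
      stringsAsFactors = FALSE
    )
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
  } else {
    toEmpty <- function(x) ifelse(is.na(x), "", x)
    toBool <- function(x) ifelse(x, "T", "F")
    out <- data.frame(
      sequence_id = df$contig_id,
      cell_id = df$barcode,
      locus = df$locus,
      v_call = toEmpty(df$v_call),
      d_call = toEmpty(df$d_call),
      j_call = toEmpty(df$j_call),
      c_call = toEmpty(df$c_call),
      junction = ifelse(is.na(df$cdr3_nt), "",
                        paste0("TGT", df$cdr3_nt, "TGG")),
      junction_aa = ifelse(is.na(df$cdr3_aa), "",
                           paste0("C", df$cdr3_aa, "W")),
      productive = toBool(df$productive),
      complete_vdj = toBool(df$full_length),
      high_confidence = toBool(df$high_confidence),
      is_cell = toBool(df$is_cell),
      duplicate_count = df$umis,
      consensus_count = df$reads,
      stringsAsFactors = FALSE
    )
    utils::write.table(out, path, sep = "\t", row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}
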