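# Fixture builders and independent brute-force oracles used across tests.

suppressPackageStartupMessages({
  library(S4Vectors)
  library(IRanges)
  library(Biostrings)
})

# Internal-schema contig rows with sensible defaults and recycling.
contigRows <- function(barcode, locus = "IGH", v_call = "IGHV1-1",
                       d_call = NA_character_, j_call = "IGHJ1",
                       c_call = NA_character_, cdr3_aa = NA_character_,
                       cdr3_nt = NA_character_, productive = TRUE,
                       full_length = TRUE, high_confidence = TRUE,
                       is_cell = TRUE, umis = 4L, reads = 40L,
                       contig_id = NULL) {
  n <- if (length(barcode) == 0L) 0L else
    max(lengths(list(barcode, locus, v_call, d_call, j_call, c_call,
                     cdr3_aa, cdr3_nt, productive, full_length,
                     high_confidence, is_cell, umis, reads)))
  if (is.null(contig_id))
    contig_id <- sprintf("ctg%06d", seq_len(n) + sample.int(1e6, 1))
  data.frame(barcode = rep_len(barcode, n),
             contig_id = contig_id,
             locus = rep_len(locus, n),
             v_call = rep_len(v_call, n), d_call = rep_len(d_call, n),
             j_call = rep_len(j_call, n), c_call = rep_len(c_call, n),
             cdr3_aa = rep_len(cdr3_aa, n), cdr3_nt = rep_len(cdr3_nt, n),
             productive = rep_len(productive, n),
             full_length = rep_len(full_length, n),
             high_confidence = rep_len(high_confidence, n),
             is_cell = rep_len(is_cell, n),
             umis = rep_len(as.integer(umis), n),
             reads = rep_len(as.integer(reads), n),
             stringsAsFactors = FALSE)
}

# Random QC-passing contig table with heavy key collisions, <= 200 rows.
# cdr3 nt/aa pairs include synonymous codon variants so the three key
# modes genuinely differ.
randomContigTable <- function(seed, maxRows = 200L) {
  set.seed(seed)
  n <- sample.int(maxRows, 1L)
  cdr3Pairs <- list(
    c(NA_character_, NA_character_), c("GCTAAA", "AK"), c("GCCAAA", "AK"), c("TTTAAA", "FK"),
    c("GCTAAG", "AK"), c("TGGCCC", "WP")
  )
  loci <- sample(c("IGH", "IGK", "IGL"), n, replace = TRUE)
  pick <- sample.int(length(cdr3Pairs), n, replace = TRUE)
  vpool <- function(l) paste0(l, "V", 1:4, "-X")
  jpool <- function(l) paste0(l, "J", 1:3)
  df <- contigRows(
    barcode = paste0("BC", sample.int(8, n, replace = TRUE)),
    locus = loci,
    v_call = vapply(loci, function(l) sample(vpool(l), 1), character(1)),
    d_call = ifelse(loci == "IGH", paste0("IGHD", sample.int(3, n, TRUE)),
                    NA_character_),
    j_call = vapply(loci, function(l) sample(jpool(l), 1), character(1)),
    c_call = ifelse(loci == "IGH",
                    sample(c("IGHM", "IGHD", "IGHG1", NA), n, TRUE),
                    ifelse(loci == "IGK", "IGKC", "IGLC")),
    cdr3_nt = vapply(pick, function(i) cdr3Pairs[[i]][1], character(1)),
    cdr3_aa = vapply(pick, function(i) cdr3Pairs[[i]][2], character(1)),
    umis = sample(2:9, n, replace = TRUE),
    contig_id = sprintf("s%d_ctg%04d", seed, seq_len(n))
  )
  ContigTable(df, source = paste0("random-", seed))
}

# Independent nested-loop dedup oracle: per (barcode, locus), count
# distinct pattern tuples by linear scan, no set machinery shared with
# the implementation.
brutePatternCounts <- function(df, locus, mode) {
  counts <- list()
  for (r in seq_len(nrow(df))) {
    if (df$locus[r] != locus) next
    if (is.na(df$v_call[r]) || is.na(df$j_call[r])) next
    cdr3 <- switch(mode,
      gene_only = "",
      gene_cdr3nt = if (is.na(df$cdr3_nt[r])) "" else df$cdr3_nt[r],
      gene_cdr3aa = if (is.na(df$cdr3_aa[r])) "" else df$cdr3_aa[r])
    d <- if (is.na(df$d_call[r])) "" else df$d_call[r]
    tup <- paste(df$v_call[r], d, df$j_call[r], cdr3, sep = "~")
    bc <- df$barcode[r]
    if (is.null(counts[[bc]])) counts[[bc]] <- character()
    seen <- FALSE
    for (t in counts[[bc]]) if (t == tup) { seen <- TRUE; break }
    if (!seen) counts[[bc]] <- c(counts[[bc]], tup)
  }
  vapply(counts, length, integer(1))
}

# Plain O(nm) Smith-Waterman local alignment score (linear gap penalty),
# the oracle for best-identity germline assignment.
bruteLocalScore <- function(a, b, match = 1, mismatch = -1, gap = 2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      H[i + 1, j + 1] <- max(0, H[i, j] + s, H[i, j + 1] - gap,
                             H[i + 1, j] - gap)
      if (H[i + 1, j + 1] > best) best <- H[i + 1, j + 1]
    }
  }
  best
}

# Tiny registry with short segments (for alignment oracle tests), built
# through the public FASTA path.
smallRegistry <- function(seed = 42, nV = 3L, nD = 2L, nJ = 2L,
                          vLen = 40L, dLen = 10L, jLen = 15L) {
  set.seed(seed)
  rseq <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE),
                              collapse = "")
  fa <- tempfile(fileext = ".fa")
  nm <- c(sprintf("IGHV%d-S1", seq_len(nV)), sprintf("IGHD%d-S1", seq_len(nD)),
          sprintf("IGHJ%d-S1", seq_len(nJ)))
  lens <- c(rep(vLen, nV), rep(dLen, nD), rep(jLen, nJ))
  writeLines(unlist(lapply(seq_along(nm), function(i)
    c(paste0(">", nm[i]), rseq(lens[i])))), fa)
  readRegistryFasta(fa)
}

# Fast vectorized builder for large toy cohorts reproducing printed
# numerator/denominator ratios.
vMultiplicityTable <- function(locus, nCells, nMulti) {
  v1 <- paste0(locus, "V1-A")
  v2 <- paste0(locus, "V2-B")
  bc <- sprintf("%s_cell%05d", locus, seq_len(nCells))
  base <- contigRows(barcode = bc, locus = locus, v_call = v1,
                     j_call = paste0(locus, "J1"),
                     contig_id = paste0(bc, "_c1"))
  extra <- contigRows(barcode = bc[seq_len(nMulti)], locus = locus,
                      v_call = v2, j_call = NA_character_,
                      full_length = FALSE,
                      contig_id = paste0(bc[seq_len(nMulti)], "_c2"))
  ContigTable(rbind(base, extra), source = "toy")
}
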