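#' @include AllClasses.R
NULL

# Keep only the first listed gene of a multi-allele call and strip the
# IMGT allele suffix ("IGHV1-69*01,IGHV1-69*02" -> "IGHV1-69"). Gene-level
# identity is the granularity of the whole analysis.
normalizeGeneCall <- function(x) {
  x <- sub(",.*$", "", x)
  x <- sub("\\*[^*]*$", "", x)
  x[!is.na(x) & !nzchar(x)] <- NA_character_
  x
}

# Collapse an IGH constant-region gene to class level (IGHG1..4 -> IGHG,
# IGHA1,2 -> IGHA). Non-IGH / unknown constant genes map to NA.
collapseIgClass <- function(c_call) {
  out <- sub("^(IGHG)[0-9]*$", "\\1", c_call)
  out <- sub("^(IGHA)[0-9]*$", "\\1", out)
  out[!out %in% .IGH_CLASSES] <- NA_character_
  out
}

# Encode a recombination pattern as a sortable string key under the active
# key mode. NA fields encode as "".
patternKeys <- function(locus, v, d, j, cdr3_nt, cdr3_aa,
                        mode = c("gene_cdr3nt", "gene_only", "gene_cdr3aa")) {
  mode <- match.arg(mode)
  cdr3 <- switch(mode,
    gene_only = rep("", length(v)),
    gene_cdr3nt = ifelse(is.na(cdr3_nt), "", cdr3_nt),
    gene_cdr3aa = ifelse(is.na(cdr3_aa), "", cdr3_aa)
  )
  paste(locus, ifelse(is.na(v), "", v), ifelse(is.na(d), "", d),
        ifelse(is.na(j), "", j), cdr3, sep = "|")
}

# Split "locus|v|d|j|cdr3" keys back into a data.frame.
parsePatternKeys <- function(keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  parts <- lapply(parts, function(p) { length(p) <- 5L; p })
  m <- do.call(rbind, parts)
  if (is.null(m)) m <- matrix(character(), ncol = 5)
  out <- data.frame(locus = m[, 1], v = m[, 2], d = m[, 3], j = m[, 4],
                    cdr3 = m[, 5], stringsAsFactors = FALSE)
  out[is.na(out)] <- ""
  out
}

# Evaluate an expression with a temporary RNG state so generators are
# reproducible without clobbering the caller's stream.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Sorted unique character set (lexicographic, C locale for reproducibility).
sortedSet <- function(x) {
  x <- unique(x[!is.na(x)])
  if (!length(x)) return(character())
  sort(x, method = "radix")
}
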