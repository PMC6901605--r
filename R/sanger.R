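#' @include AllClasses.R utils.R simulate.R
#' @importFrom Biostrings DNAString DNAStringSet pairwiseAlignment score
#'   pattern subject pid readDNAStringSet writeXStringSet width
NULL

# Scoring matrix over ACGTN: configurable match/mismatch, N scores 0
# against everything so ambiguous bases neither help nor hurt.
.nucMatrix <- function(match, mismatch) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

#' Assign germline V/D/J segments to Sanger amplicon reads
#'
#' For each read, the V and J segments are assigned by highest-scoring
#' local alignment against the registry pool of the read's locus (scoring
#' match +1, mismatch -1, gap -2 by default), the J search being
#' restricted to the sequence downstream of the aligned V. The D segment
#' is searched only within the inter-V-J window and assigned only when
#' its alignment covers at least \code{dMinLength} nucleotides (D
#' segments are short, so shorter hits are noise); otherwise it is left
#' null. Assignments whose percent identity falls below
#' \code{minIdentity} yield status \code{no_V} / \code{no_J}. When two
#' segments score identically, strict mode reports status
#' \code{ambiguous} while lenient mode picks the lexicographically
#' smallest name. The junction -- the region between the end of the
#' aligned V and the start of the aligned J -- is recorded as the CDR3
#' proxy for nucleotide-level pattern keys.
#'
#' @param reads A named \code{DNAStringSet}, character vector of
#'   sequences, or path to a FASTA file. Names of the form
#'   \code{"cell|read"} supply both identifiers; otherwise pass
#'   \code{cellIds}.
#' @param registry A [GermlineRegistry-class].
#' @param cellIds Optional character vector of cell identifiers parallel
#'   to \code{reads}.
#' @param lociHint Optional per-read locus hint (\code{"IGH"},
#'   \code{"IGK"}, \code{"IGL"}, or \code{"unknown"}); from the primer
#'   set used. Unknown-locus reads are assigned to the locus whose V pool
#'   aligns best.
#' @param minIdentity Minimum percent identity for V and J assignment.
#' @param match,mismatch,gapPenalty Local-alignment scoring parameters.
#' @param vMinLength,jMinLength Minimum aligned length for a V / J hit.
#'   Percent identity of a local alignment is meaningless for very short
#'   hits (any exact 10-mer is 100\% identical), so hits must also cover
#'   a sensible fraction of the segment.
#' @param dMinLength Minimum aligned length for a D assignment.
#' @param tieMode \code{"strict"} (equal best scores give status
#'   \code{ambiguous}) or \code{"lenient"} (smallest name wins).
#' @return A \code{data.frame} of pattern calls: \code{cell_id, read_id,
#'   locus, v_call, d_call, j_call, v_identity, j_identity, junction,
#'   status}.
#' @export
assignGermline <- function(reads, registry, cellIds = NULL, lociHint = NULL,
                           minIdentity = 80, match = 1, mismatch = -1,
                           gapPenalty = 2, vMinLength = 60, jMinLength = 20,
                           dMinLength = 8,
                           tieMode = c("strict", "lenient")) {
  tieMode <- match.arg(tieMode)
  stopifnot(is(registry, "GermlineRegistry"))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- readDNAStringSet(reads)
  if (is.character(reads)) reads <- DNAStringSet(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  if (is.null(cellIds)) {
    cellIds <- ifelse(grepl("|", ids, fixed = TRUE),
                      sub("\\|.*$", "", ids), ids)
  }
  readIds <- ifelse(grepl("|", ids, fixed = TRUE),
                    sub("^.*\\|", "", ids), ids)
  stopifnot(length(cellIds) == length(reads))
  if (is.null(lociHint)) lociHint <- rep("unknown", length(reads))
  mat <- .nucMatrix(match, mismatch)
  info <- registry@info
  poolOf <- function(locus, type) {
    nm <- info$name[info$locus == locus & info$type == type]
    registry@sequences[nm]
  }
  out <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    out[[i]] <- .assignOne(reads[[i]], cellIds[i], readIds[i], lociHint[i],
                           poolOf, mat, minIdentity, gapPenalty,
                           vMinLength, jMinLength, dMinLength, tieMode)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Align a pool against a subject; return list(best index/indices, score,
# identity, subject start/end) or NULL for an empty pool.
.bestHit <- function(pool, subjectSeq, mat, gapPenalty) {
  if (!length(pool) || length(subjectSeq) == 0) return(NULL)
  aln <- pairwiseAlignment(pool, subjectSeq, type = "local",
                           substitutionMatrix = mat,
                           gapOpening = 0, gapExtension = gapPenalty)
  sc <- score(aln)
  best <- which(sc == max(sc))
  list(idx = best, score = max(sc), aln = aln)
}

.assignOne <- function(readSeq, cellId, readId, hint, poolOf, mat,
                       minIdentity, gapPenalty, vMinLength, jMinLength,
                       dMinLength, tieMode) {
  row <- data.frame(cell_id = cellId, read_id = readId,
                    locus = NA_character_, v_call = NA_character_,
                    d_call = NA_character_, j_call = NA_character_,
                    v_identity = NA_real_, j_identity = NA_real_,
                    junction = NA_character_, status = "no_V",
                    stringsAsFactors = FALSE)
  loci <- if (!is.null(hint) && hint %in% .LOCI) hint else .LOCI
  # best V over the candidate loci decides the locus
  vBest <- NULL; vLocus <- NA_character_
  for (locus in loci) {
    hit <- .bestHit(poolOf(locus, "V"), readSeq, mat, gapPenalty)
    if (!is.null(hit) && (is.null(vBest) || hit$score > vBest$score)) {
      vBest <- hit; vLocus <- locus
    }
  }
  if (is.null(vBest)) return(row)
  vPool <- poolOf(vLocus, "V")
  if (length(vBest$idx) > 1L) {
    if (tieMode == "strict") { row$status <- "ambiguous"; return(row) }
    vBest$idx <- vBest$idx[order(names(vPool)[vBest$idx],
                                 method = "radix")][1L]
  }
  vAln <- vBest$aln[vBest$idx[1L]]
  vIdent <- pid(vAln, type = "PID1")
  if (vIdent < minIdentity || score(vAln) <= 0 ||
      width(pattern(vAln)) < vMinLength) return(row)
  row$locus <- vLocus
  row$v_call <- names(vPool)[vBest$idx[1L]]
  row$v_identity <- vIdent
  vEnd <- Biostrings::end(subject(vAln))
  # J is searched downstream of the aligned V only
  rest <- if (vEnd < length(readSeq))
    Biostrings::subseq(readSeq, vEnd + 1L, length(readSeq)) else NULL
  row$status <- "no_J"
  if (is.null(rest) || length(rest) == 0) return(row)
  jPool <- poolOf(vLocus, "J")
  jHit <- .bestHit(jPool, rest, mat, gapPenalty)
  if (is.null(jHit)) return(row)
  if (length(jHit$idx) > 1L) {
    if (tieMode == "strict") { row$status <- "ambiguous"; return(row) }
    jHit$idx <- jHit$idx[order(names(jPool)[jHit$idx], method = "radix")][1L]
  }
  jAln <- jHit$aln[jHit$idx[1L]]
  jIdent <- pid(jAln, type = "PID1")
  if (jIdent < minIdentity || score(jAln) <= 0 ||
      width(pattern(jAln)) < jMinLength) return(row)
  row$j_call <- names(jPool)[jHit$idx[1L]]
  row$j_identity <- jIdent
  jStart <- vEnd + Biostrings::start(subject(jAln))
  row$status <- "assigned"
  window <- if (jStart - 1L >= vEnd + 1L)
    Biostrings::subseq(readSeq, vEnd + 1L, jStart - 1L) else NULL
  row$junction <- if (is.null(window)) "" else as.character(window)
  if (row$locus == "IGH" && !is.null(window) &&
      length(window) >= dMinLength) {
    dPool <- poolOf("IGH", "D")
    if (length(dPool)) {
      dAln <- pairwiseAlignment(dPool, window, type = "local",
                                substitutionMatrix = mat,
                                gapOpening = 0, gapExtension = gapPenalty)
      cov <- width(pattern(dAln))
      ok <- which(cov >= dMinLength)
      if (length(ok)) {
        sc <- score(dAln)[ok]
        bestD <- ok[sc == max(sc)]
        if (length(bestD) > 1L) {
          if (tieMode == "lenient")
            bestD <- bestD[order(names(dPool)[bestD], method = "radix")][1L]
          else bestD <- integer()   # strict: leave D unassigned on tie
        }
        if (length(bestD) == 1L) row$d_call <- names(dPool)[bestD]
      }
    }
  }
  row
}

#' Collapse pattern calls to unique per-cell recombination patterns
#'
#' Deduplicates assigned calls per cell under the chosen key mode, with
#' the same semantics as [buildCellProfiles()]: a pattern is its locus,
#' V/D/J calls, and (for the nucleotide mode) the junction recorded as
#' the CDR3 proxy. Unassigned, ambiguous, or partial calls are skipped.
#'
#' @param calls Output of [assignGermline()].
#' @param keyMode Pattern key mode, as in [buildCellProfiles()].
#' @return A named \code{CharacterList}: per cell, the sorted set of
#'   pattern keys.
#' @export
collapseUniquePatterns <- function(calls,
                                   keyMode = c("gene_cdr3nt", "gene_only",
                                               "gene_cdr3aa")) {
  keyMode <- match.arg(keyMode)
  ok <- calls$status == "assigned"
  calls <- calls[ok, , drop = FALSE]
  aa <- rep(NA_character_, nrow(calls))
  if (keyMode == "gene_cdr3aa" && nrow(calls)) {
    inFrame <- !is.na(calls$junction) & nchar(calls$junction) %% 3L == 0L &
      nchar(calls$junction) > 0L
    aa[inFrame] <- as.character(suppressWarnings(
      translate(DNAStringSet(calls$junction[inFrame]))))
  }
  keys <- patternKeys(calls$locus, calls$v_call, calls$d_call, calls$j_call,
                      calls$junction, aa, mode = keyMode)
  cells <- sortedSet(calls$cell_id)
  CharacterList(lapply(split(keys, factor(calls$cell_id, levels = cells)),
                       sortedSet))
}

#' Germline segment-usage spectrum
#'
#' Counts how often each registry segment appears across a collection of
#' unique recombination patterns, per pool (locus x V/D/J), including
#' zero-count registry entries, with relative frequencies normalized
#' within each pool.
#'
#' @param patterns A \code{CharacterList} (e.g. from
#'   [collapseUniquePatterns()] or [patternsByLocus()]) or character
#'   vector of \code{"locus|v|d|j|cdr3"} pattern keys.
#' @param registry A [GermlineRegistry-class].
#' @return \code{data.frame} with columns \code{locus, type, segment,
#'   count, frequency}; frequencies sum to 1 within each non-empty pool.
#' @export
segmentUsageSpectrum <- function(patterns, registry) {
  stopifnot(is(registry, "GermlineRegistry"))
  keys <- unlist(as.list(patterns), use.names = FALSE)
  if (is.null(keys)) keys <- character()
  parsed <- parsePatternKeys(keys)
  info <- as.data.frame(registry@info)
  counts <- integer(nrow(info))
  names(counts) <- info$name
  for (col in c("v", "d", "j")) {
    seg <- parsed[[col]][nzchar(parsed[[col]])]
    tab <- table(seg)
    hit <- names(tab)[names(tab) %in% names(counts)]
    counts[hit] <- counts[hit] + as.integer(tab[hit])
  }
  out <- data.frame(locus = info$locus, type = info$type,
                    segment = info$name, count = unname(counts),
                    stringsAsFactors = FALSE)
  out$frequency <- NA_real_
  for (locus in unique(out$locus)) {
    for (type in unique(out$type[out$locus == locus])) {
      sel <- out$locus == locus & out$type == type
      tot <- sum(out$count[sel])
      if (tot > 0) out$frequency[sel] <- out$count[sel] / tot
    }
  }
  out[order(out$locus, out$type, out$segment, method = "radix"), ,
      drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Simulate Sanger amplicon reads from a germline registry
#'
#' Builds, per cell, the requested number of distinct V(D)J
#' rearrangements (full V + junction N/D nucleotides + full J, so the
#' amplicon's inter-V-J region is the junction) and emits
#' \code{readsPerPattern} reads per rearrangement, optionally with random
#' substitutions. Read names are \code{"cell|read"}. Ground truth records
#' each cell's pattern keys with the junction convention of
#' [assignGermline()] (the region strictly between V and J).
#'
#' @param registry A [GermlineRegistry-class].
#' @param patternCounts Integer vector: number of distinct heavy-chain
#'   patterns per cell (one element per cell).
#' @param locus Locus to simulate.
#' @param readsPerPattern Reads emitted per pattern.
#' @param mutationRate Per-base substitution probability.
#' @param seed RNG seed.
#' @return \code{list(reads = DNAStringSet, truth = CharacterList per
#'   cell, calls = data.frame of true segment assignments per read)}.
#' @export
simulateAmplicons <- function(registry, patternCounts, locus = "IGH",
                              readsPerPattern = 3L, mutationRate = 0,
                              seed = 1L) {
  stopifnot(is(registry, "GermlineRegistry"), all(patternCounts >= 1))
  withSeed(seed, {
    info <- registry@info
    seqs <- character(); nm <- character()
    truth <- vector("list", length(patternCounts))
    tv <- character(); td <- character(); tj <- character()
    tcell <- character(); tread <- character()
    for (i in seq_along(patternCounts)) {
      cellId <- sprintf("cell%03d", i)
      keys <- character(patternCounts[i])
      for (q in seq_len(patternCounts[i])) {
        repeat {
          p <- .drawPattern(locus, registry)
          vseq <- as.character(registry@sequences[[p$v]])
          jseq <- as.character(registry@sequences[[p$j]])
          # the amplicon's inter-V-J region (assignGermline's junction
          # convention) is the drawn junction minus its 6-nt V/J flanks
          mid <- substr(p$cdr3_nt, 7L, nchar(p$cdr3_nt) - 6L)
          key <- patternKeys(locus, p$v, p$d, p$j, mid, NA, "gene_cdr3nt")
          if (!key %in% keys) break
        }
        keys[q] <- key
        amplicon <- paste0(vseq, mid, jseq)
        for (r in seq_len(readsPerPattern)) {
          s <- amplicon
          if (mutationRate > 0) {
            nmut <- stats::rbinom(1, nchar(s), mutationRate)
            if (nmut > 0) {
              pos <- sample.int(nchar(s), nmut)
              for (pp in pos) {
                cur <- substr(s, pp, pp)
                substr(s, pp, pp) <- sample(setdiff(c("A", "C", "G", "T"),
                                                    cur), 1L)
              }
            }
          }
          seqs <- c(seqs, s)
          rid <- sprintf("read%04d", length(seqs))
          nm <- c(nm, paste0(cellId, "|", rid))
          tcell <- c(tcell, cellId); tread <- c(tread, rid)
          tv <- c(tv, p$v); td <- c(td, if (is.na(p$d)) "" else p$d)
          tj <- c(tj, p$j)
        }
      }
      truth[[i]] <- sort(keys, method = "radix")
      names(truth)[i] <- cellId
    }
    reads <- DNAStringSet(seqs)
    names(reads) <- nm
    list(reads = reads,
         truth = CharacterList(truth),
         calls = data.frame(cell_id = tcell, read_id = tread, v_call = tv,
                            d_call = td, j_call = tj,
                            stringsAsFactors = FALSE))
  })
}

#' Read or write a germline registry as FASTA
#'
#' Segment names must be IMGT-style (\code{IGHV...}, \code{IGKJ...}):
#' the first three characters give the locus and the fourth the segment
#' type.
#'
#' @param path FASTA file path.
#' @return [readRegistryFasta()]: a [GermlineRegistry-class].
#' @export
readRegistryFasta <- function(path) {
  sset <- readDNAStringSet(path)
  nm <- names(sset)
  locus <- substr(nm, 1, 3)
  type <- substr(nm, 4, 4)
  bad <- !(locus %in% .LOCI) | !(type %in% c("V", "D", "J"))
  if (any(bad))
    stop("cannot parse locus/type from segment name(s): ",
         paste(utils::head(nm[bad], 3), collapse = ", "))
  new("GermlineRegistry", sequences = sset,
      info = DataFrame(name = nm, locus = locus, type = type))
}

#' @rdname readRegistryFasta
#' @param registry A [GermlineRegistry-class] to write.
#' @export
writeRegistryFasta <- function(registry, path) {
  writeXStringSet(registry@sequences, path)
  invisible(path)
}
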