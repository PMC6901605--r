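#' @include AllClasses.R utils.R
#' @importFrom IRanges CharacterList
#' @importFrom S4Vectors DataFrame
NULL

.QC_FLAGS <- c("is_cell", "high_confidence", "productive", "full_length")

#' QC-filter a contig table
#'
#' Retains contigs passing all enabled QC flags. The \code{"default"}
#' preset requires \code{is_cell & high_confidence & productive &
#' full_length}, matching the semantics of Cell Ranger's filtered output;
#' the \code{"v_segment"} preset drops the \code{full_length} requirement
#' so that partially assembled transcripts (where the V segment was
#' recovered but the full V(D)J could not be assembled) still contribute
#' their V gene to per-cell V-segment counting. An optional UMI floor
#' (off by default) can be enabled to probe sensitivity to ambient-RNA
#' contamination.
#'
#' @param table A [ContigTable-class].
#' @param preset \code{"default"}, \code{"v_segment"}, or \code{"none"}.
#' @param flags Explicit character vector of flags to require (overrides
#'   \code{preset}); any subset of
#'   \code{c("is_cell","high_confidence","productive","full_length")}.
#' @param umiFloor If non-NULL, additionally require \code{umis >= umiFloor}.
#' @return A filtered [ContigTable-class] (possibly empty).
#' @export
qcFilter <- function(table, preset = c("default", "v_segment", "none"),
                     flags = NULL, umiFloor = NULL) {
  stopifnot(is(table, "ContigTable"))
  preset <- match.arg(preset)
  if (is.null(flags)) {
    flags <- switch(preset,
      default = .QC_FLAGS,
      v_segment = setdiff(.QC_FLAGS, "full_length"),
      none = character()
    )
  }
  bad <- setdiff(flags, .QC_FLAGS)
  if (length(bad)) stop("unknown QC flag(s): ", paste(bad, collapse = ", "))
  df <- table@contigs
  keep <- rep(TRUE, nrow(df))
  for (f in flags) keep <- keep & !is.na(df[[f]]) & df[[f]]
  if (!is.null(umiFloor))
    keep <- keep & !is.na(df$umis) & df$umis >= umiFloor
  out <- table
  out@contigs <- df[keep, , drop = FALSE]
  rownames(out@contigs) <- NULL
  out
}

#' Build per-cell recombination-pattern profiles
#'
#' Aggregates a QC-filtered contig table into one [CellProfileSet-class]
#' profile per distinct barcode. A contig contributes a recombination
#' pattern when both its V and J calls are present (the D call may be
#' missing, as it always is for light chains); identical patterns under
#' the active key mode are deduplicated. Every contig with a V call
#' contributes to the per-locus V-gene set regardless of J, which is what
#' makes V-segment-level multiplicity counting on the \code{"v_segment"}
#' QC preset independent of full V(D)J assembly. IGH patterns whose contig
#' carries a constant-region call are additionally assigned to that Ig
#' class (collapsed to class level, e.g. IGHG2 -> IGHG); contigs with no
#' constant call count toward the per-locus pattern sets but not the
#' per-class sets.
#'
#' @param table A QC-filtered [ContigTable-class].
#' @param keyMode Pattern identity key: \code{"gene_cdr3nt"} (default;
#'   gene calls plus CDR3 nucleotide sequence), \code{"gene_only"}, or
#'   \code{"gene_cdr3aa"}.
#' @return A [CellProfileSet-class]; barcodes and pattern sets are sorted
#'   lexicographically for reproducible reports.
#' @export
buildCellProfiles <- function(table,
                              keyMode = c("gene_cdr3nt", "gene_only",
                                          "gene_cdr3aa")) {
  stopifnot(is(table, "ContigTable"))
  keyMode <- match.arg(keyMode)
  df <- table@contigs
  bcs <- sortedSet(df$barcode)
  fac <- factor(df$barcode, levels = bcs)
  cells <- DataFrame(barcode = bcs)
  keys <- patternKeys(df$locus, df$v_call, df$d_call, df$j_call,
                      df$cdr3_nt, df$cdr3_aa, mode = keyMode)
  patEligible <- !is.na(df$v_call) & !is.na(df$j_call)
  for (locus in .LOCI) {
    sel <- df$locus == locus & patEligible
    cells[[paste0("patterns_", locus)]] <-
      CharacterList(lapply(split(keys[sel], fac[sel]), sortedSet))
    vsel <- df$locus == locus & !is.na(df$v_call)
    cells[[paste0("vgenes_", locus)]] <-
      CharacterList(lapply(split(df$v_call[vsel], fac[vsel]), sortedSet))
  }
  cls <- collapseIgClass(df$c_call)
  csel <- df$locus == "IGH" & !is.na(cls)
  cells$c_classes <- CharacterList(lapply(split(cls[csel], fac[csel]),
                                          sortedSet))
  cells$subset <- rep("unassigned", length(bcs))
  cpSel <- csel & patEligible
  cp <- DataFrame(barcode = df$barcode[cpSel], c_class = cls[cpSel],
                  pattern = keys[cpSel])
  cp <- unique(cp)
  cp <- cp[order(cp$barcode, cp$c_class, cp$pattern, method = "radix"), ,
           drop = FALSE]
  rownames(cp) <- NULL
  new("CellProfileSet", cells = cells, classPatterns = cp, keyMode = keyMode)
}

#' Per-cell pattern multiplicity category
#'
#' Bins the number of distinct recombination patterns a cell expresses at
#' one locus into the categories used for cohort reporting: cells with one,
#' two, or three-or-more patterns. Cells with zero patterns at the locus
#' are reported as \code{"zero"} and are excluded from that locus's
#' denominator downstream, which is why per-locus cell counts differ.
#'
#' @param profiles A [CellProfileSet-class].
#' @param locus \code{"IGH"}, \code{"IGK"}, or \code{"IGL"}.
#' @return A factor parallel to [barcodes()] with levels
#'   \code{zero, one, two, three_or_more}.
#' @export
multiplicityCategory <- function(profiles, locus = c("IGH", "IGK", "IGL")) {
  stopifnot(is(profiles, "CellProfileSet"))
  locus <- match.arg(locus)
  n <- lengths(profiles@cells[[paste0("patterns_", locus)]])
  cut(n, breaks = c(-0.5, 0.5, 1.5, 2.5, Inf),
      labels = c("zero", "one", "two", "three_or_more"))
}

#' Per-cell light-chain usage class
#'
#' Classifies each cell as expressing only kappa, only lambda, both light
#' chains, or neither, from the non-emptiness of its IGK and IGL pattern
#' sets. Co-expression of kappa and lambda ("both") violates the classical
#' isotypic-exclusion rule.
#'
#' @param profiles A [CellProfileSet-class].
#' @return A factor with levels
#'   \code{kappa_only, lambda_only, both, none}.
#' @export
lightChainUsage <- function(profiles) {
  stopifnot(is(profiles, "CellProfileSet"))
  k <- lengths(profiles@cells$patterns_IGK) > 0
  l <- lengths(profiles@cells$patterns_IGL) > 0
  factor(ifelse(k & l, "both",
         ifelse(k, "kappa_only",
         ifelse(l, "lambda_only", "none"))),
         levels = c("kappa_only", "lambda_only", "both", "none"))
}

#' Per-cell V-segment multiplicity
#'
#' Number of distinct germline V genes (gene-level, allele-stripped)
#' observed among a cell's contigs at one locus. Meaningful on profiles
#' built with the \code{"v_segment"} QC preset, where partially assembled
#' transcripts still contribute their V gene.
#'
#' @param profiles A [CellProfileSet-class].
#' @param locus \code{"IGH"}, \code{"IGK"}, or \code{"IGL"}.
#' @return Integer vector parallel to [barcodes()].
#' @export
vSegmentMultiplicity <- function(profiles, locus = c("IGH", "IGK", "IGL")) {
  stopifnot(is(profiles, "CellProfileSet"))
  locus <- match.arg(locus)
  unname(lengths(profiles@cells[[paste0("vgenes_", locus)]]))
}

# Resolve a groupBy argument into a factor over cells: NULL -> one group,
# column names of the cell DataFrame -> their interaction, or an explicit
# vector of length nCells.
.resolveGroups <- function(profiles, groupBy) {
  n <- nrow(profiles@cells)
  if (is.null(groupBy)) return(factor(rep("all", n)))
  if (is.character(groupBy) && length(groupBy) < n &&
      all(groupBy %in% colnames(profiles@cells))) {
    vals <- lapply(groupBy, function(g) as.character(profiles@cells[[g]]))
    return(factor(do.call(paste, c(vals, sep = "."))))
  }
  if (length(groupBy) != n)
    stop("groupBy must be cell-data column names or a vector of length nCells")
  factor(as.character(groupBy))
}

.summaryRow <- function(group, metric, category, num, den) {
  data.frame(group = group, metric = metric, category = category,
             numerator = as.integer(num), denominator = as.integer(den),
             proportion = ifelse(den > 0, num / den, NA_real_),
             stringsAsFactors = FALSE)
}

.tabulateMetric <- function(cats, groups, metric, levels, denomMask) {
  out <- list()
  for (g in levels(groups)) {
    inG <- groups == g
    den <- sum(inG & denomMask)
    for (lv in levels) {
      num <- sum(inG & denomMask & cats == lv, na.rm = TRUE)
      out[[length(out) + 1L]] <- .summaryRow(g, metric, lv, num, den)
    }
  }
  do.call(rbind, out)
}

#' Cohort-level proportion tables
#'
#' Emits per-group numerator/denominator/proportion rows for the standard
#' repertoire metrics. Denominators are per-metric: for the per-locus
#' multiplicity metrics only cells with at least one pattern at that locus
#' count; for light-chain usage only cells with at least one light-chain
#' pattern; for V-segment multiplicity only cells with at least one V gene
#' at that locus. Within each partitioning metric the category numerators
#' sum exactly to the denominator.
#'
#' @param profiles A [CellProfileSet-class].
#' @param groupBy \code{NULL} (one group), column names of the cell data
#'   (e.g. \code{"subset"}), or an explicit grouping vector of length
#'   [nCells()].
#' @param metrics Any of \code{"multiplicity"} (categories one / two /
#'   three_or_more per locus), \code{"light_chain"} (kappa_only /
#'   lambda_only / both), \code{"v_multiplicity"} (one / multiple per
#'   locus).
#' @param loci Loci for the per-locus metrics.
#' @return A \code{data.frame} with columns \code{group, metric, category,
#'   numerator, denominator, proportion}; deterministic row order.
#' @examples
#' tab <- ContigTable(data.frame(
#'   barcode = c("c1", "c1", "c2"), contig_id = paste0("k", 1:3),
#'   locus = "IGH", v_call = c("IGHV1-2", "IGHV3-7", "IGHV1-2"),
#'   d_call = "IGHD2-2", j_call = "IGHJ4", c_call = "IGHM",
#'   cdr3_aa = NA, cdr3_nt = c("GCTAAA", "GCTCCC", "GCTAAA"),
#'   productive = TRUE, full_length = TRUE, high_confidence = TRUE,
#'   is_cell = TRUE, umis = 4L, reads = 50L))
#' summarizeCohort(buildCellProfiles(tab), metrics = "multiplicity",
#'                 loci = "IGH")
#' @export
summarizeCohort <- function(profiles, groupBy = NULL,
                            metrics = c("multiplicity", "light_chain",
                                        "v_multiplicity"),
                            loci = c("IGH", "IGK", "IGL")) {
  stopifnot(is(profiles, "CellProfileSet"))
  if (nrow(profiles@cells) < 1L) stop("at least one profile required")
  metrics <- match.arg(metrics, several.ok = TRUE)
  loci <- match.arg(loci, several.ok = TRUE)
  groups <- .resolveGroups(profiles, groupBy)
  out <- list()
  if ("multiplicity" %in% metrics) {
    for (locus in loci) {
      cats <- multiplicityCategory(profiles, locus)
      out[[length(out) + 1L]] <- .tabulateMetric(
        cats, groups, paste0("multiplicity_", locus),
        c("one", "two", "three_or_more"), denomMask = cats != "zero")
    }
  }
  if ("light_chain" %in% metrics) {
    usage <- lightChainUsage(profiles)
    out[[length(out) + 1L]] <- .tabulateMetric(
      usage, groups, "light_chain",
      c("kappa_only", "lambda_only", "both"), denomMask = usage != "none")
  }
  if ("v_multiplicity" %in% metrics) {
    for (locus in loci) {
      nv <- vSegmentMultiplicity(profiles, locus)
      cats <- factor(ifelse(nv >= 2, "multiple", "one"),
                     levels = c("one", "multiple"))
      out[[length(out) + 1L]] <- .tabulateMetric(
        cats, groups, paste0("v_multiplicity_", locus),
        c("one", "multiple"), denomMask = nv > 0)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
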