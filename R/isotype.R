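#' @include AllClasses.R repertoire.R
#' @importFrom IRanges CharacterList
NULL

.PAIR_LABELS <- c("IgM_IgD", "IgM_IgG", "IgG_IgA", "other_pair")

#' Per-cell Ig class count category
#'
#' Bins the number of distinct heavy-chain constant-region classes (IgM,
#' IgD, IgG, IgA, IgE at class level) a cell expresses into one / two /
#' three (three or more collapses into \code{"three"}). Cells with no
#' classed IGH contig cannot be binned and return \code{NA}; they are
#' excluded from class-count denominators.
#'
#' @param profiles A [CellProfileSet-class].
#' @return Factor parallel to [barcodes()] with levels
#'   \code{one, two, three}, NA where no class was observed.
#' @export
classCountCategory <- function(profiles) {
  stopifnot(is(profiles, "CellProfileSet"))
  n <- lengths(profiles@cells$c_classes)
  out <- cut(n, breaks = c(0.5, 1.5, 2.5, Inf),
             labels = c("one", "two", "three"))
  out
}

#' Label the Ig class combination of a two-class cell
#'
#' The enumerated combinations are IgM+IgD (the naive co-expression pair),
#' IgM+IgG, IgG+IgA (the memory switch pair); every other pair (IgM+IgA,
#' IgM+IgE, IgD+IgG, IgD+IgA, IgD+IgE, IgG+IgE, IgA+IgE) is
#' \code{other_pair}.
#'
#' @param x A character vector of exactly two class names (e.g.
#'   \code{c("IGHM","IGHD")}), or a [CellProfileSet-class].
#' @param strict For a profile set: error if any cell does not have
#'   exactly two classes (\code{TRUE}), or return NA for those cells.
#' @return Factor with levels
#'   \code{IgM_IgD, IgM_IgG, IgG_IgA, other_pair}.
#' @export
classPairLabel <- function(x, strict = TRUE) {
  if (is(x, "CellProfileSet")) {
    sets <- as.list(x@cells$c_classes)
    bad <- lengths(sets) != 2L
    if (strict && any(bad))
      stop(sum(bad), " cell(s) do not have exactly two Ig classes")
    lab <- rep(NA_character_, length(sets))
    lab[!bad] <- vapply(sets[!bad], .pairLabelOne, character(1))
    return(factor(lab, levels = .PAIR_LABELS))
  }
  if (length(x) != 2L) stop("a class pair must have exactly two classes")
  factor(.pairLabelOne(x), levels = .PAIR_LABELS)
}

.pairLabelOne <- function(classes) {
  s <- sort(classes)
  if (identical(s, sort(c("IGHM", "IGHD")))) return("IgM_IgD")
  if (identical(s, sort(c("IGHM", "IGHG")))) return("IgM_IgG")
  if (identical(s, sort(c("IGHG", "IGHA")))) return("IgG_IgA")
  "other_pair"
}

#' Cross-class V(D)J pattern sharing within single cells
#'
#' For every cell expressing two or more Ig classes, intersects the
#' per-class pattern sets of each class pair under the profile set's
#' active key mode. Under classical class-switch recombination the
#' rearranged VDJ is untouched, so classes within one cell should share
#' their pattern; disjoint per-class patterns indicate the opposite.
#'
#' @param profiles A [CellProfileSet-class] (its per-class pattern
#'   assignments must be populated, i.e. built from contigs with constant
#'   calls).
#' @return A \code{DataFrame} with one row per (cell, class pair):
#'   \code{barcode, class_a, class_b} (pair orientation normalized to the
#'   fixed class order IGHM, IGHD, IGHG, IGHA, IGHE), \code{CharacterList}
#'   columns \code{shared, a_only, b_only}, and logical \code{shares_any}.
#' @export
crossClassSharing <- function(profiles) {
  stopifnot(is(profiles, "CellProfileSet"))
  cells <- profiles@cells
  cp <- profiles@classPatterns
  multi <- cells$barcode[lengths(cells$c_classes) >= 2L]
  rows <- list()
  for (bc in multi) {
    classes <- cells$c_classes[[match(bc, cells$barcode)]]
    classes <- classes[order(match(classes, .IGH_CLASSES))]
    pats <- lapply(classes, function(cl)
      cp$pattern[cp$barcode == bc & cp$c_class == cl])
    names(pats) <- classes
    for (i in seq_len(length(classes) - 1L)) {
      for (j in seq(i + 1L, length(classes))) {
        a <- pats[[i]]; b <- pats[[j]]
        shared <- sortedSet(intersect(a, b))
        rows[[length(rows) + 1L]] <- list(
          barcode = bc, class_a = classes[i], class_b = classes[j],
          shared = shared, a_only = sortedSet(setdiff(a, b)),
          b_only = sortedSet(setdiff(b, a)),
          shares_any = length(shared) > 0L)
      }
    }
  }
  if (!length(rows)) {
    return(DataFrame(barcode = character(), class_a = character(),
                     class_b = character(),
                     shared = CharacterList(),
                     a_only = CharacterList(), b_only = CharacterList(),
                     shares_any = logical()))
  }
  DataFrame(
    barcode = vapply(rows, `[[`, character(1), "barcode"),
    class_a = vapply(rows, `[[`, character(1), "class_a"),
    class_b = vapply(rows, `[[`, character(1), "class_b"),
    shared = CharacterList(lapply(rows, `[[`, "shared")),
    a_only = CharacterList(lapply(rows, `[[`, "a_only")),
    b_only = CharacterList(lapply(rows, `[[`, "b_only")),
    shares_any = vapply(rows, `[[`, logical(1), "shares_any")
  )
}

#' Cohort summary of Ig class usage and cross-class pattern sharing
#'
#' Per group, reports (i) the class-count composition (one / two / three
#' classes; denominator = cells with at least one classed IGH contig),
#' (ii) the class-pair composition among two-class cells, and (iii) the
#' fraction of multi-class cells in which any class pair shares at least
#' one identical pattern (1 under classical CSR, 0 when every class
#' carries its own patterns).
#'
#' @param profiles A [CellProfileSet-class].
#' @param groupBy As in [summarizeCohort()].
#' @return A \code{data.frame} in the [summarizeCohort()] schema.
#' @export
sharingSummary <- function(profiles, groupBy = NULL) {
  stopifnot(is(profiles, "CellProfileSet"))
  groups <- .resolveGroups(profiles, groupBy)
  out <- list()
  cats <- classCountCategory(profiles)
  out[[1L]] <- .tabulateMetric(cats, groups, "class_count",
                               c("one", "two", "three"),
                               denomMask = !is.na(cats))
  pair <- classPairLabel(profiles, strict = FALSE)
  out[[2L]] <- .tabulateMetric(pair, groups, "class_pair", .PAIR_LABELS,
                               denomMask = !is.na(pair))
  rep_ <- crossClassSharing(profiles)
  shareByCell <- tapply(rep_$shares_any, rep_$barcode, any)
  isMulti <- lengths(profiles@cells$c_classes) >= 2L
  shares <- rep(FALSE, nrow(profiles@cells))
  idx <- match(names(shareByCell), profiles@cells$barcode)
  shares[idx] <- as.logical(shareByCell)
  cats2 <- factor(ifelse(shares, "shares_any", "disjoint"),
                  levels = c("shares_any", "disjoint"))
  out[[3L]] <- .tabulateMetric(cats2, groups, "cross_class_sharing",
                               c("shares_any", "disjoint"),
                               denomMask = isMulti)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
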