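#' @include AllClasses.R utils.R repertoire.R
#' @importFrom IRanges CharacterList
#' @importFrom S4Vectors DataFrame
#' @importFrom Biostrings DNAStringSet DNAString subseq translate width
#' @importFrom stats rnorm rpois runif
NULL

#' SimConfig: parameters of the synthetic scVDJ generator
#'
#' Holds every knob of the truth-tracked simulator: cohort size, the
#' B-cell subset mixture, per-locus distributions of the number of
#' distinct recombination patterns per cell, the kappa/lambda
#' co-expression rate, the Ig class-count distribution and class
#' composition rules per subset, the probability that a multi-class
#' cell's classes share one pattern (0 = each class carries its own
#' patterns, 1 = classical CSR), doublet and ambient-contamination rates,
#' germline registry pool sizes, and the marker separation of the paired
#' expression matrix. Construct with [simConfig()]; all probability
#' vectors must sum to one.
#'
#' @seealso [simConfig()], [simulateCells()], [buildRegistry()]
#' @export
setClass("SimConfig",
  slots = c(
    nCells = "integer", seed = "integer",
    subsetMix = "numeric",
    patternRates = "list",
    kappaLambdaRate = "numeric", kappaBias = "numeric",
    classCountDist = "list", classComposition = "list",
    crossClassShareRate = "numeric",
    doubletRate = "numeric", ambientRate = "numeric",
    registrySizes = "list",
    markerSeparation = "numeric"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  okDist <- function(p) all(p >= 0 & p <= 1) && abs(sum(p) - 1) < 1e-8
  if (object@nCells < 1L) msg <- c(msg, "nCells must be >= 1")
  if (!okDist(object@subsetMix) ||
      !identical(sort(names(object@subsetMix)), sort(c("naive", "memory", "plasma"))))
    msg <- c(msg, "subsetMix must be a probability vector over naive/memory/plasma")
  for (locus in .LOCI)
    for (s in names(object@patternRates[[locus]]))
      if (!okDist(object@patternRates[[locus]][[s]]))
        msg <- c(msg, paste("patternRates must sum to 1 for", locus, s))
  if (!all(object@kappaLambdaRate >= 0 & object@kappaLambdaRate <= 1))
    msg <- c(msg, "kappaLambdaRate must be in [0,1]")
  if (object@kappaBias < 0 || object@kappaBias > 1)
    msg <- c(msg, "kappaBias must be in [0,1]")
  for (s in names(object@classCountDist))
    if (!okDist(object@classCountDist[[s]]))
      msg <- c(msg, paste("classCountDist must sum to 1 for", s))
  if (object@crossClassShareRate < 0 || object@crossClassShareRate > 1)
    msg <- c(msg, "crossClassShareRate must be in [0,1]")
  if (object@doubletRate < 0 || object@doubletRate > 0.5)
    msg <- c(msg, "doubletRate must be in [0, 0.5]")
  if (object@ambientRate < 0 || object@ambientRate > 1)
    msg <- c(msg, "ambientRate must be in [0,1]")
  for (locus in .LOCI) {
    sz <- object@registrySizes[[locus]]
    if (is.null(sz) || sz["V"] < 1 || sz["J"] < 1 || sz["D"] < 0)
      msg <- c(msg, paste("registry sizes invalid for", locus))
    if (locus != "IGH" && sz["D"] != 0)
      msg <- c(msg, "light-chain loci must have an empty D pool")
  }
  if (object@markerSeparation <= 0)
    msg <- c(msg, "markerSeparation must be positive")
  if (length(msg)) msg else TRUE
})

# Expand a per-subset parameter given either as one value/vector (applied
# to all subsets) or as a named list/vector per subset.
.perSubset <- function(x, what) {
  subs <- c("naive", "memory", "plasma")
  if (is.list(x)) {
    if (!all(subs %in% names(x))) stop(what, " must cover all subsets")
    return(x[subs])
  }
  if (is.numeric(x) && !is.null(names(x)) && all(subs %in% names(x)))
    return(as.list(x[subs]))
  stats::setNames(rep(list(x), 3L), subs)
}

#' Construct a simulator configuration
#'
#' Defaults emulate the structure of a healthy-donor peripheral-blood
#' CD19+ cohort: a naive/memory-dominated subset mixture with rare plasma
#' cells; per-locus two-pattern rates of 7\% (IGH), 11\% (IGK) and 16\%
#' (IGL) with three-pattern rates below 0.5\%; per-subset kappa/lambda
#' co-expression (higher in naive than memory cells); naive class pairs
#' dominated by IgM+IgD and memory pairs by IgG+IgA with IgM+IgG allowed
#' in both; per-class pattern sets disjoint by default
#' (\code{crossClassShareRate = 0}); and no doublet or ambient artifacts
#' unless requested.
#'
#' @param nCells Number of native cells to simulate.
#' @param seed Default RNG seed for [buildRegistry()]/[simulateCells()].
#' @param subsetMix Named probabilities over naive/memory/plasma.
#' @param patternRates List per locus; each entry either a length-3
#'   probability vector over 1/2/3 patterns (applied to all subsets) or a
#'   per-subset list of such vectors.
#' @param kappaLambdaRate Probability a cell expresses both light chains;
#'   single value or per-subset named vector.
#' @param kappaBias Probability a single-light-chain cell uses kappa.
#' @param classCountDist Per-subset (or shared) length-3 probability
#'   vector over 1/2/3 Ig classes.
#' @param classComposition Per-subset list with named probability vectors
#'   \code{singles}, \code{pairs}, \code{triples}; pair/triple names join
#'   classes with \code{"+"}.
#' @param crossClassShareRate Probability that a multi-class cell's
#'   classes all share its pattern set.
#' @param doubletRate,ambientRate Artifact rates applied by
#'   [simulateCells()] via [injectDoublets()]/[injectAmbient()].
#' @param registrySizes List per locus of \code{c(V=, D=, J=)} pool sizes.
#' @param markerSeparation Distance, in units of the unit-variance noise
#'   SD, between positive and negative marker means in the paired
#'   expression matrix.
#' @return A validated [SimConfig-class].
#' @export
simConfig <- function(nCells = 1000L, seed = 1L,
                      subsetMix = c(naive = 0.54, memory = 0.45, plasma = 0.01),
                      patternRates = list(
                        IGH = c(0.927, 0.07, 0.003),
                        IGK = c(0.8865, 0.11, 0.0035),
                        IGL = c(0.8356, 0.16, 0.0044)),
                      kappaLambdaRate = c(naive = 0.28, memory = 0.12,
                                          plasma = 0.20),
                      kappaBias = 0.6,
                      classCountDist = list(
                        naive = c(0.765, 0.22, 0.015),
                        memory = c(0.595, 0.37, 0.035),
                        plasma = c(0.80, 0.18, 0.02)),
                      classComposition = NULL,
                      crossClassShareRate = 0,
                      doubletRate = 0, ambientRate = 0,
                      registrySizes = list(IGH = c(V = 20, D = 10, J = 6),
                                           IGK = c(V = 15, D = 0, J = 5),
                                           IGL = c(V = 15, D = 0, J = 5)),
                      markerSeparation = 5) {
  if (is.null(classComposition)) {
    classComposition <- list(
      naive = list(
        singles = c(IGHM = 0.9, IGHD = 0.1),
        pairs = c("IGHM+IGHD" = 0.7, "IGHM+IGHG" = 0.3),
        triples = c("IGHM+IGHD+IGHG" = 1)),
      memory = list(
        singles = c(IGHG = 0.6, IGHA = 0.25, IGHM = 0.15),
        pairs = c("IGHG+IGHA" = 0.55, "IGHM+IGHG" = 0.35,
                  "IGHD+IGHG" = 0.05, "IGHM+IGHA" = 0.05),
        triples = c("IGHM+IGHG+IGHA" = 1)),
      plasma = list(
        singles = c(IGHG = 0.7, IGHA = 0.3),
        pairs = c("IGHG+IGHA" = 0.8, "IGHM+IGHG" = 0.2),
        triples = c("IGHM+IGHG+IGHA" = 1))
    )
  }
  pr <- lapply(.LOCI, function(locus) {
    x <- patternRates[[locus]]
    if (is.null(x)) stop("patternRates missing for ", locus)
    .perSubset(x, paste0("patternRates$", locus))
  })
  names(pr) <- .LOCI
  cfg <- new("SimConfig",
    nCells = as.integer(nCells), seed = as.integer(seed),
    subsetMix = subsetMix, patternRates = pr,
    kappaLambdaRate = unlist(.perSubset(kappaLambdaRate, "kappaLambdaRate")),
    kappaBias = kappaBias,
    classCountDist = .perSubset(classCountDist, "classCountDist"),
    classComposition = .perSubset(classComposition, "classComposition"),
    crossClassShareRate = crossClassShareRate,
    doubletRate = doubletRate, ambientRate = ambientRate,
    registrySizes = registrySizes,
    markerSeparation = markerSeparation)
  validObject(cfg)
  cfg
}

.randomSeq <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

#' Build a synthetic germline segment registry
#'
#' Generates named V/D/J nucleotide pools per locus with IMGT-style
#' synthetic names (\code{IGHV1-S1}, \code{IGKJ2-S1}, ...). Segment
#' lengths are fixed: V 300 nt, D 20 nt, J 50 nt. Reproducible given the
#' seed; the D pool is empty for the light-chain loci.
#'
#' @param config A [SimConfig-class] (pool sizes are taken from it).
#' @param seed RNG seed; defaults to the config's seed.
#' @return A [GermlineRegistry-class].
#' @export
buildRegistry <- function(config = simConfig(), seed = config@seed) {
  withSeed(seed, {
    names_ <- character(); loci <- character(); types <- character()
    seqs <- character()
    for (locus in .LOCI) {
      sz <- config@registrySizes[[locus]]
      for (type in c("V", "D", "J")) {
        n <- as.integer(sz[type])
        if (n < 1L) next
        len <- c(V = 300L, D = 20L, J = 50L)[type]
        names_ <- c(names_, sprintf("%s%s%d-S1", locus, type, seq_len(n)))
        loci <- c(loci, rep(locus, n))
        types <- c(types, rep(type, n))
        seqs <- c(seqs, .randomSeq(n, len))
      }
    }
    sset <- DNAStringSet(seqs)
    names(sset) <- names_
    new("GermlineRegistry", sequences = sset,
        info = DataFrame(name = names_, locus = loci, type = types))
  })
}

# Draw one recombination pattern at a locus: segment names plus a CDR3
# junction = last 6 nt of V + N1 + (D for IGH) + N2 + first 6 nt of J,
# with N lengths 0-6 constrained so the junction stays in frame.
.drawPattern <- function(locus, registry) {
  info <- registry@info
  pick <- function(type) {
    pool <- info$name[info$locus == locus & info$type == type]
    if (!length(pool)) return(NA_character_)
    pool[sample.int(length(pool), 1L)]
  }
  v <- pick("V"); j <- pick("J")
  d <- if (locus == "IGH") pick("D") else NA_character_
  vseq <- as.character(registry@sequences[[v]])
  jseq <- as.character(registry@sequences[[j]])
  dseq <- if (!is.na(d)) as.character(registry@sequences[[d]]) else ""
  n1 <- sample(0:6, 1L)
  fixedLen <- 12L + nchar(dseq) + n1
  valid <- (0:6)[(fixedLen + 0:6) %% 3L == 0L]
  n2 <- valid[sample.int(length(valid), 1L)]
  rand <- function(k) if (k > 0) paste(sample(c("A", "C", "G", "T"), k,
                                              replace = TRUE), collapse = "") else ""
  junction <- paste0(substr(vseq, nchar(vseq) - 5L, nchar(vseq)),
                     rand(n1), dseq, rand(n2), substr(jseq, 1L, 6L))
  list(v = v, d = d, j = j, cdr3_nt = junction)
}

.drawDistinctPatterns <- function(k, locus, registry) {
  pats <- list(); keys <- character()
  while (length(pats) < k) {
    p <- .drawPattern(locus, registry)
    key <- paste(p$v, p$d, p$j, p$cdr3_nt, sep = "|")
    if (!key %in% keys) { pats[[length(pats) + 1L]] <- p; keys <- c(keys, key) }
  }
  pats
}

.sampleName <- function(p) names(p)[sample.int(length(p), 1L, prob = p)]

#' Simulate a truth-tracked single-cell V(D)J dataset
#'
#' Generates, per cell: a subset drawn from the configured mixture; a
#' number of distinct recombination patterns per expressed locus drawn
#' from the configured per-locus distribution (IGH always expressed; both
#' light chains with the configured kappa/lambda co-expression
#' probability, otherwise one); an Ig class set drawn from the class-count
#' distribution and composition rules; and a paired marker-expression
#' profile with per-subset Gaussian positive markers (CD38 high only in
#' plasma, CD27 positive in memory and plasma, IGHM/IGHD positive in
#' naive cells) and structural-zero negative markers. With probability
#' \code{crossClassShareRate} all of a multi-class cell's classes carry
#' the cell's full IGH pattern set (classical CSR limit); otherwise each
#' class receives its own disjoint patterns, in which case the realized
#' class count is capped at the realized IGH pattern count (a cell cannot
#' have more disjointly-rearranged classes than patterns). Every contig
#' is productive, full-length, high-confidence and cell-associated, with
#' at least two UMIs; injected ambient contigs carry one UMI.
#'
#' Doublets and ambient contamination are then injected at the configured
#' rates. The truth table records, per emitted barcode, the true subset,
#' pattern sets per locus (as \code{gene_cdr3nt} keys), class set,
#' provenance (\code{native}, \code{doublet}, or
#' \code{ambient_contaminated}) and doublet constituents.
#'
#' @param config A [SimConfig-class].
#' @param registry A [GermlineRegistry-class]; defaults to
#'   \code{buildRegistry(config, seed)}.
#' @param seed RNG seed; defaults to the config's seed. Identical
#'   (config, seed) give byte-identical outputs.
#' @return A list with elements \code{contigs} ([ContigTable-class]),
#'   \code{expression} (\code{SummarizedExperiment}, genes x cells) and
#'   \code{truth} (\code{DataFrame}).
#' @export
simulateCells <- function(config, registry = NULL, seed = config@seed) {
  stopifnot(is(config, "SimConfig"))
  if (is.null(registry)) registry <- buildRegistry(config, seed)
  sim <- withSeed(seed, .simulateNative(config, registry))
  if (config@doubletRate > 0) {
    res <- injectDoublets(sim$contigs, sim$truth, config@doubletRate,
                          seed = seed + 1L)
    sim$contigs <- res$contigs; sim$truth <- res$truth
  }
  if (config@ambientRate > 0) {
    res <- injectAmbient(sim$contigs, sim$truth, config@ambientRate,
                         seed = seed + 2L)
    sim$contigs <- res$contigs; sim$truth <- res$truth
  }
  sim
}

.simulateNative <- function(config, registry) {
  n <- config@nCells
  subs <- sample(names(config@subsetMix), n, replace = TRUE,
                 prob = config@subsetMix)
  bcs <- sprintf("BC%06d-1", seq_len(n))
  col <- function() vector("list", n)
  acc <- list(barcode = col(), locus = col(), v = col(), d = col(),
              j = col(), c = col(), cdr3 = col())
  truthPat <- list(IGH = col(), IGK = col(), IGL = col())
  truthClasses <- col()
  markers <- c("CD19", "CD27", "CD38", "IGHM", "IGHD")
  expr <- matrix(0, nrow = length(markers), ncol = n,
                 dimnames = list(markers, bcs))
  sep <- config@markerSeparation
  for (i in seq_len(n)) {
    s <- subs[i]
    lightBoth <- runif(1) < config@kappaLambdaRate[s]
    lightLoci <- if (lightBoth) c("IGK", "IGL")
                 else if (runif(1) < config@kappaBias) "IGK" else "IGL"
    loci <- c("IGH", lightLoci)
    pats <- list()
    for (locus in loci) {
      k <- sample.int(3L, 1L, prob = config@patternRates[[locus]][[s]])
      pats[[locus]] <- .drawDistinctPatterns(k, locus, registry)
      truthPat[[locus]][[i]] <- sort(vapply(pats[[locus]], function(p)
        patternKeys(locus, p$v, p$d, p$j, p$cdr3_nt, NA, "gene_cdr3nt"),
        character(1)), method = "radix")
    }
    kIGH <- length(pats$IGH)
    cc <- config@classCountDist[[s]]
    cDraw <- sample.int(3L, 1L, prob = cc)
    shared <- cDraw >= 2L && runif(1) < config@crossClassShareRate
    cEff <- if (shared) cDraw else min(cDraw, kIGH)
    comp <- config@classComposition[[s]]
    pool <- switch(cEff, comp$singles, comp$pairs, comp$triples)
    if (is.null(pool) || !length(pool))
      stop("class composition rules cannot produce a ", cEff,
           "-class cell for subset '", s, "'")
    classes <- strsplit(.sampleName(pool), "+", fixed = TRUE)[[1]]
    truthClasses[[i]] <- sort(classes, method = "radix")
    # contig rows: IGH patterns x their class assignment
    rows_locus <- character(); rows_v <- character(); rows_d <- character()
    rows_j <- character(); rows_c <- character(); rows_cdr3 <- character()
    emit <- function(locus, p, ccall) {
      rows_locus <<- c(rows_locus, locus); rows_v <<- c(rows_v, p$v)
      rows_d <<- c(rows_d, p$d); rows_j <<- c(rows_j, p$j)
      rows_c <<- c(rows_c, ccall); rows_cdr3 <<- c(rows_cdr3, p$cdr3_nt)
    }
    if (shared) {
      for (cl in classes) for (p in pats$IGH) emit("IGH", p, cl)
    } else {
      assign_ <- c(classes,
                   if (kIGH > length(classes))
                     classes[sample.int(length(classes), kIGH - length(classes),
                                        replace = TRUE)])
      for (q in seq_len(kIGH)) emit("IGH", pats$IGH[[q]], assign_[q])
    }
    for (locus in lightLoci)
      for (p in pats[[locus]])
        emit(locus, p, if (locus == "IGK") "IGKC" else "IGLC")
    m <- length(rows_locus)
    acc$barcode[[i]] <- rep(bcs[i], m)
    acc$locus[[i]] <- rows_locus; acc$v[[i]] <- rows_v
    acc$d[[i]] <- rows_d; acc$j[[i]] <- rows_j; acc$c[[i]] <- rows_c
    acc$cdr3[[i]] <- rows_cdr3
    # marker profile: positive markers Gaussian around the separation,
    # negative markers structural zeros (dropout-style)
    posv <- function(mean) max(rnorm(1, mean, 1), 0.01)
    expr["CD19", i] <- posv(sep)
    if (s %in% c("memory", "plasma")) expr["CD27", i] <- posv(sep)
    expr["CD38", i] <- if (s == "plasma") posv(2.5 * sep) else posv(0.5 * sep)
    if (s == "naive") {
      expr["IGHM", i] <- posv(sep); expr["IGHD", i] <- posv(sep)
    }
  }
  barcode <- unlist(acc$barcode); locus <- unlist(acc$locus)
  v <- unlist(acc$v); d <- unlist(acc$d); j <- unlist(acc$j)
  ccall <- unlist(acc$c); cdr3 <- unlist(acc$cdr3)
  nrow_ <- length(barcode)
  aa <- as.character(suppressWarnings(translate(DNAStringSet(cdr3))))
  umis <- 2L + rpois(nrow_, 6)
  df <- data.frame(
    barcode = barcode,
    contig_id = paste0(barcode, "_contig_", unlist(lapply(acc$barcode, seq_along))),
    locus = locus, v_call = v, d_call = d, j_call = j, c_call = ccall,
    cdr3_aa = aa, cdr3_nt = cdr3,
    productive = TRUE, full_length = TRUE, high_confidence = TRUE,
    is_cell = TRUE, umis = umis, reads = umis * (15L + rpois(nrow_, 10)),
    stringsAsFactors = FALSE
  )
  emptyCL <- function(x) CharacterList(lapply(x, function(e)
    if (is.null(e)) character() else e))
  truth <- DataFrame(
    barcode = bcs, subset = subs,
    patterns_IGH = emptyCL(truthPat$IGH),
    patterns_IGK = emptyCL(truthPat$IGK),
    patterns_IGL = emptyCL(truthPat$IGL),
    classes = emptyCL(truthClasses),
    provenance = rep("native", n),
    constituents = rep(NA_character_, n),
    n_ambient = integer(n)
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(logcounts = expr),
    colData = DataFrame(barcode = bcs, subset = subs))
  list(contigs = ContigTable(df, dialect = "tenx_csv", source = "simulateCells"),
       expression = se, truth = truth)
}

#' Merge random cell pairs into doublet barcodes
#'
#' Selects disjoint cell pairs uniformly at random and merges each pair's
#' contigs under the first constituent's barcode, so that the emitted
#' fraction of doublet barcodes is \code{rate}. The truth table marks the
#' merged entry \code{provenance = "doublet"}, records both constituent
#' barcodes, and unions the pattern and class sets (the merged barcode
#' genuinely contains both cells' chains).
#'
#' @param table A [ContigTable-class].
#' @param truth The matching truth \code{DataFrame}.
#' @param rate Fraction of emitted barcodes that are doublets, in
#'   [0, 0.5].
#' @param seed RNG seed.
#' @return \code{list(contigs=, truth=)}.
#' @export
injectDoublets <- function(table, truth, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 0.5)
  n <- nrow(truth)
  nPairs <- round(rate * n / (1 + rate))
  if (rate == 0 || nPairs < 1L)
    return(list(contigs = table, truth = truth))
  withSeed(seed, {
    chosen <- sample(truth$barcode, 2L * nPairs)
    keepBc <- chosen[seq_len(nPairs)]
    dropBc <- chosen[nPairs + seq_len(nPairs)]
    df <- table@contigs
    map <- stats::setNames(keepBc, dropBc)
    hit <- df$barcode %in% dropBc
    df$barcode[hit] <- unname(map[df$barcode[hit]])
    iKeep <- match(keepBc, truth$barcode)
    iDrop <- match(dropBc, truth$barcode)
    for (colp in c("patterns_IGH", "patterns_IGK", "patterns_IGL", "classes")) {
      merged <- mapply(function(a, b) sortedSet(c(a, b)),
                       as.list(truth[[colp]][iKeep]),
                       as.list(truth[[colp]][iDrop]), SIMPLIFY = FALSE)
      truth[[colp]][iKeep] <- CharacterList(merged)
    }
    truth$provenance[iKeep] <- "doublet"
    truth$constituents[iKeep] <- paste(keepBc, dropBc, sep = ";")
    truth <- truth[-iDrop, , drop = FALSE]
    out <- table
    out@contigs <- df
    list(contigs = out, truth = truth)
  })
}

#' Inject ambient-RNA contaminant contigs
#'
#' With the given per-cell probability, appends to a barcode one contig
#' copied from a random other cell's pool, carrying a single UMI (ambient
#' molecules are low-copy). The recipient's truth entry is marked
#' \code{ambient_contaminated} (doublet provenance is preserved) and its
#' contaminant count incremented; the true pattern sets are left at the
#' native values, since the contaminant is an artifact, not biology.
#'
#' @param table A [ContigTable-class].
#' @param truth The matching truth \code{DataFrame}.
#' @param rate Per-cell contamination probability in [0, 1].
#' @param seed RNG seed.
#' @return \code{list(contigs=, truth=)}.
#' @export
injectAmbient <- function(table, truth, rate, seed = 1L) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(list(contigs = table, truth = truth))
  withSeed(seed, {
    df <- table@contigs
    bcs <- truth$barcode
    hitCells <- which(runif(length(bcs)) < rate)
    newRows <- list()
    for (idx in hitCells) {
      donorRows <- which(df$barcode != bcs[idx])
      if (!length(donorRows)) next
      src <- df[donorRows[sample.int(length(donorRows), 1L)], , drop = FALSE]
      src$barcode <- bcs[idx]
      src$contig_id <- sprintf("%s_ambient_%d", bcs[idx],
                               truth$n_ambient[idx] + 1L)
      src$umis <- 1L
      src$reads <- 5L
      newRows[[length(newRows) + 1L]] <- src
      truth$n_ambient[idx] <- truth$n_ambient[idx] + 1L
      if (truth$provenance[idx] == "native")
        truth$provenance[idx] <- "ambient_contaminated"
    }
    out <- table
    if (length(newRows))
      out@contigs <- rbind(df, do.call(rbind, newRows))
    rownames(out@contigs) <- NULL
    validObject(out)
    list(contigs = out, truth = truth)
  })
}

#' Marker rules matched to a simulator configuration
#'
#' Returns the [MarkerRuleSet-class] whose CD38-high cutoff sits at the
#' midpoint between the simulated plasma and non-plasma CD38 means. With
#' the default 5-SD marker separation this classifies simulated subsets
#' essentially perfectly; use it when evaluating the classifier against
#' the simulator's truth labels instead of the percentile fallback, which
#' assumes the plasma fraction matches the percentile.
#'
#' @param config A [SimConfig-class].
#' @return A [MarkerRuleSet-class].
#' @export
markerRulesFromConfig <- function(config) {
  markerRules(positiveCutoff = 0,
              cd38HighCutoff = 1.5 * config@markerSeparation)
}
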