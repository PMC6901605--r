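test_that("unmutated amplicons are re-assigned to their source segments at 100% identity", {
  cfg <- simConfig(seed = 17,
                   registrySizes = list(IGH = c(V = 8, D = 4, J = 3),
                                        IGK = c(V = 3, D = 0, J = 2),
                                        IGL = c(V = 3, D = 0, J = 2)))
  reg <- buildRegistry(cfg)
  amp <- simulateAmplicons(reg, patternCounts = c(2, 1, 3), seed = 18)
  calls <- assignGermline(amp$reads, reg)
  expect_true(all(calls$status == "assigned"))
  expect_true(all(calls$v_identity == 100))
  expect_true(all(calls$j_identity == 100))
  truthCalls <- amp$calls
  expect_identical(calls$v_call, truthCalls$v_call)
  expect_identical(calls$j_call, truthCalls$j_call)
  # D segments are 20 nt, well over the 8 nt coverage floor
  expect_identical(calls$d_call, truthCalls$d_call)
})

test_that("V/J choice agrees with an exhaustive Smith-Waterman oracle", {
  for (seed in 1:20) {
    reg <- smallRegistry(seed = 100 + seed)
    amp <- simulateAmplicons(reg, patternCounts = 1L, readsPerPattern = 1L,
                             mutationRate = 0.03, seed = seed)
    read <- as.character(amp$reads[[1]])
    call <- assignGermline(amp$reads, reg, tieMode = "lenient",
                           vMinLength = 20, jMinLength = 10)
    info <- as.data.frame(segmentInfo(reg))
    vNames <- info$name[info$type == "V"]
    vScores <- vapply(vNames, function(nm)
      bruteLocalScore(as.character(segmentSequences(reg)[[nm]]), read),
      numeric(1))
    bestV <- sort(vNames[vScores == max(vScores)])[1]
    expect_identical(call$v_call, bestV,
                     label = paste("seed", seed))
  }
})

test_that("sequences unrelated to the registry are not assigned", {
  reg <- buildRegistry(simConfig(seed = 2))
  set.seed(7)
  junk <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  call <- assignGermline(junk, reg)
  expect_identical(call$status, "no_V")
  expect_true(is.na(call$v_call))
})

test_that("score ties are ambiguous under strict mode, name-ordered under lenient", {
  set.seed(12)
  vseq <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  jseq <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">IGHV2-S1", vseq, ">IGHV1-S1", vseq, ">IGHJ1-S1", jseq), fa)
  reg <- readRegistryFasta(fa)
  read <- paste0(vseq, "ACGTAC", jseq)
  strict <- assignGermline(read, reg, tieMode = "strict")
  expect_identical(strict$status, "ambiguous")
  lenient <- assignGermline(read, reg, tieMode = "lenient")
  expect_identical(lenient$v_call, "IGHV1-S1")   # lexicographically smallest
  expect_identical(lenient$status, "assigned")
  expect_identical(lenient$junction, "ACGTAC")   # inter-V-J window
})

test_that("most assignments survive 5% random substitutions", {
  cfg <- simConfig(seed = 41,
                   registrySizes = list(IGH = c(V = 10, D = 5, J = 4),
                                        IGK = c(V = 2, D = 0, J = 2),
                                        IGL = c(V = 2, D = 0, J = 2)))
  reg <- buildRegistry(cfg)
  amp <- simulateAmplicons(reg, patternCounts = rep(2L, 25),
                           readsPerPattern = 3L, mutationRate = 0.05,
                           seed = 42)
  calls <- assignGermline(amp$reads, reg, lociHint = rep("IGH", length(amp$reads)))
  ok <- calls$status == "assigned" &
    calls$v_call == amp$calls$v_call & calls$j_call == amp$calls$j_call
  expect_gte(mean(ok), 0.95)
})

test_that("per-cell pattern collapse equals repertoire-style dedup and truth", {
  cfg <- simConfig(seed = 51,
                   registrySizes = list(IGH = c(V = 6, D = 3, J = 3),
                                        IGK = c(V = 2, D = 0, J = 2),
                                        IGL = c(V = 2, D = 0, J = 2)))
  reg <- buildRegistry(cfg)
  counts <- c(1L, 2L, 8L)
  amp <- simulateAmplicons(reg, patternCounts = counts,
                           readsPerPattern = 2L, seed = 52)
  calls <- assignGermline(amp$reads, reg)
  pats <- collapseUniquePatterns(calls)
  expect_identical(unname(lengths(pats)), counts)
  expect_identical(lapply(as.list(pats), as.character),
                   lapply(as.list(amp$truth), as.character))
  # the same calls pushed through the contig path dedup identically
  df <- contigRows(calls$cell_id, locus = calls$locus,
                   v_call = calls$v_call, d_call = calls$d_call,
                   j_call = calls$j_call, cdr3_nt = calls$junction,
                   contig_id = paste0(calls$cell_id, "_", calls$read_id))
  prof <- buildCellProfiles(ContigTable(df))
  expect_identical(unname(lengths(patternsByLocus(prof, "IGH"))),
                   unname(lengths(pats)))
  # an 8-pattern cell lands in the top multiplicity bin
  cats <- multiplicityCategory(prof, "IGH")
  expect_identical(as.character(cats[match("cell003", barcodes(prof))]),
                   "three_or_more")
})

test_that("segment usage spectra include zero-count segments and normalize per pool", {
  reg <- smallRegistry(seed = 9, nV = 4, nD = 2, nJ = 2)
  keys <- c("IGH|IGHV1-S1|IGHD1-S1|IGHJ1-S1|GCTAAA",
            "IGH|IGHV1-S1|IGHD2-S1|IGHJ2-S1|GCCAAA",
            "IGH|IGHV2-S1||IGHJ1-S1|TTTAAA")
  spec <- segmentUsageSpectrum(keys, reg)
  vRows <- spec[spec$type == "V", ]
  expect_identical(nrow(vRows), 4L)           # zero-count entries included
  expect_identical(vRows$count[vRows$segment == "IGHV1-S1"], 2L)
  expect_identical(sum(vRows$count == 0), 2L)
  for (tp in c("V", "D", "J"))
    expect_equal(sum(spec$frequency[spec$type == tp]), 1)
  # single pattern: every used segment has frequency 1 in its pool
  one <- segmentUsageSpectrum(keys[1], reg)
  expect_identical(one$frequency[one$segment == "IGHD1-S1"], 1)
})

test_that("a uniform generator yields near-uniform segment usage", {
  cfg <- simConfig(seed = 61,
                   registrySizes = list(IGH = c(V = 5, D = 3, J = 3),
                                        IGK = c(V = 2, D = 0, J = 2),
                                        IGL = c(V = 2, D = 0, J = 2)))
  reg <- buildRegistry(cfg)
  sim <- simulateCells(simConfig(nCells = 1000, seed = 62,
                                 registrySizes = list(
                                   IGH = c(V = 5, D = 3, J = 3),
                                   IGK = c(V = 2, D = 0, J = 2),
                                   IGL = c(V = 2, D = 0, J = 2))),
                       registry = reg)
  prof <- buildCellProfiles(qcFilter(sim$contigs))
  spec <- segmentUsageSpectrum(unlist(patternsByLocus(prof, "IGH")), reg)
  vRows <- spec[spec$locus == "IGH" & spec$type == "V", ]
  n <- sum(vRows$count)
  p <- 1 / nrow(vRows)
  se <- sqrt(p * (1 - p) / n)
  expect_true(all(abs(vRows$count / n - p) < 3 * se))
})
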