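test_that("identical (config, seed) give byte-identical outputs", {
  cfg <- simConfig(nCells = 120, seed = 9, doubletRate = 0.1,
                   ambientRate = 0.1)
  s1 <- simulateCells(cfg)
  s2 <- simulateCells(cfg)
  expect_identical(serialize(as.data.frame(contigData(s1$contigs)), NULL),
                   serialize(as.data.frame(contigData(s2$contigs)), NULL))
  expect_identical(SummarizedExperiment::assay(s1$expression),
                   SummarizedExperiment::assay(s2$expression))
  expect_identical(as.list(s1$truth$patterns_IGH),
                   as.list(s2$truth$patterns_IGH))
  s3 <- simulateCells(cfg, seed = 10)
  expect_false(identical(as.data.frame(contigData(s1$contigs)),
                         as.data.frame(contigData(s3$contigs))))
})

test_that("registries are reproducible, sized as configured, and io-safe", {
  cfg <- simConfig(seed = 3)
  r1 <- buildRegistry(cfg)
  r2 <- buildRegistry(cfg)
  expect_identical(as.character(segmentSequences(r1)),
                   as.character(segmentSequences(r2)))
  info <- segmentInfo(r1)
  expect_identical(sum(info$locus == "IGH" & info$type == "V"), 20L)
  expect_identical(sum(info$locus == "IGK" & info$type == "D"), 0L)
  # segment names survive gene-call normalization unchanged
  expect_identical(polyBCR:::normalizeGeneCall(info$name), info$name)
  # and round-trip through FASTA
  f <- tempfile(fileext = ".fa")
  writeRegistryFasta(r1, f)
  r3 <- readRegistryFasta(f)
  expect_identical(as.data.frame(segmentInfo(r3)), as.data.frame(info))
  # one-V registry forces every heavy chain onto that V
  cfg1 <- simConfig(nCells = 40, seed = 4,
                    registrySizes = list(IGH = c(V = 1, D = 2, J = 2),
                                         IGK = c(V = 1, D = 0, J = 1),
                                         IGL = c(V = 1, D = 0, J = 1)))
  sim1 <- simulateCells(cfg1)
  df <- contigData(sim1$contigs)
  expect_identical(unique(df$v_call[df$locus == "IGH"]), "IGHV1-S1")
})

test_that("emitted tables pass validation and round-trip both dialects", {
  sim <- simulateCells(simConfig(nCells = 60, seed = 12))
  expect_no_error(validObject(sim$contigs))
  for (d in c("tenx", "airr")) {
    f <- tempfile()
    writeContigTable(sim$contigs, f, dialect = d)
    back <- readContigTable(f, dialect = d)
    expect_identical(as.data.frame(contigData(back)),
                     as.data.frame(contigData(sim$contigs)))
  }
})

test_that("degenerate rates produce degenerate cohorts", {
  cfg <- simConfig(nCells = 150, seed = 21,
                   patternRates = list(IGH = c(1, 0, 0), IGK = c(1, 0, 0),
                                       IGL = c(1, 0, 0)))
  prof <- buildCellProfiles(qcFilter(simulateCells(cfg)$contigs))
  s <- summarizeCohort(prof, metrics = "multiplicity", loci = "IGH")
  expect_identical(s$proportion[s$category == "one"], 1)
})

test_that("configured rates are recovered within binomial error", {
  cfg <- simConfig(nCells = 2000, seed = 8,
                   kappaLambdaRate = c(naive = 0.25, memory = 0.25,
                                       plasma = 0.25))
  prof <- buildCellProfiles(qcFilter(simulateCells(cfg)$contigs))
  s <- summarizeCohort(prof)
  p2 <- s$proportion[s$metric == "multiplicity_IGH" & s$category == "two"]
  se2 <- sqrt(0.07 * 0.93 / 2000)
  expect_lt(abs(p2 - 0.07), 3 * se2)
  pBoth <- s$proportion[s$metric == "light_chain" & s$category == "both"]
  seB <- sqrt(0.25 * 0.75 / 2000)
  expect_lt(abs(pBoth - 0.25), 3 * seB)
})

test_that("truth pattern sets match what the pipeline reconstructs on clean data", {
  sim <- simulateCells(simConfig(nCells = 80, seed = 33))
  prof <- buildCellProfiles(qcFilter(sim$contigs))
  got <- patternsByLocus(prof, "IGH")[sim$truth$barcode]
  expect_identical(unname(lapply(as.list(got), as.character)),
                   unname(lapply(as.list(sim$truth$patterns_IGH), as.character)))
})

test_that("classical-CSR limit shares every class's patterns exactly", {
  cfg <- simConfig(nCells = 200, seed = 14, crossClassShareRate = 1)
  prof <- buildCellProfiles(qcFilter(simulateCells(cfg)$contigs))
  s <- sharingSummary(prof)
  frac <- s$proportion[s$metric == "cross_class_sharing" &
                       s$category == "shares_any"]
  expect_identical(frac, 1)
})

test_that("doublet injection merges pairs and inflates multi-pattern rates monotonically", {
  base <- simConfig(nCells = 1500, seed = 77,
                    patternRates = list(IGH = c(1, 0, 0), IGK = c(1, 0, 0),
                                        IGL = c(1, 0, 0)))
  sim <- simulateCells(base)
  # rate 0 is the identity
  id <- injectDoublets(sim$contigs, sim$truth, 0)
  expect_identical(as.data.frame(contigData(id$contigs)),
                   as.data.frame(contigData(sim$contigs)))
  fracs <- vapply(c(0, 0.05, 0.1, 0.2), function(rate) {
    d <- injectDoublets(sim$contigs, sim$truth, rate, seed = 5)
    prof <- buildCellProfiles(qcFilter(d$contigs))
    cats <- multiplicityCategory(prof, "IGH")
    mean(cats %in% c("two", "three_or_more"))
  }, numeric(1))
  expect_identical(fracs[1], 0)
  expect_true(all(diff(fracs) >= 0))
  expect_gt(fracs[4], 0)
  # merged barcode's pattern set is the union of its constituents
  d <- injectDoublets(sim$contigs, sim$truth, 0.1, seed = 6)
  tr <- d$truth[d$truth$provenance == "doublet", ]
  prof <- buildCellProfiles(qcFilter(d$contigs))
  pats <- patternsByLocus(prof, "IGH")
  for (i in seq_len(min(5, nrow(tr))))
    expect_setequal(as.character(pats[[tr$barcode[i]]]),
                    as.character(tr$patterns_IGH[[i]]))
})

test_that("ambient contigs carry one UMI and a UMI floor removes them exactly", {
  sim <- simulateCells(simConfig(nCells = 300, seed = 55))
  id <- injectAmbient(sim$contigs, sim$truth, 0)
  expect_identical(as.data.frame(contigData(id$contigs)),
                   as.data.frame(contigData(sim$contigs)))
  amb <- injectAmbient(sim$contigs, sim$truth, 1, seed = 2)
  expect_gt(length(amb$contigs), length(sim$contigs))
  added <- contigData(amb$contigs)[-seq_len(length(sim$contigs)), ]
  expect_true(all(added$umis == 1L))
  # every contaminant pattern exists in some donor cell's truth
  allTruth <- unique(unlist(as.list(sim$truth$patterns_IGH)))
  addedIgh <- added[added$locus == "IGH", ]
  keys <- polyBCR:::patternKeys(addedIgh$locus, addedIgh$v_call,
                                addedIgh$d_call, addedIgh$j_call,
                                addedIgh$cdr3_nt, NA, "gene_cdr3nt")
  expect_true(all(keys %in% allTruth))
  # native estimates recovered once low-UMI contigs are floored away
  cleaned <- buildCellProfiles(qcFilter(amb$contigs, umiFloor = 2))
  native <- buildCellProfiles(qcFilter(sim$contigs))
  expect_identical(serialize(summarizeCohort(cleaned), NULL),
                   serialize(summarizeCohort(native), NULL))
  # apparent multi-pattern rate rises monotonically with contamination
  fracs <- vapply(c(0, 0.05, 0.1, 0.2), function(rate) {
    a <- injectAmbient(sim$contigs, sim$truth, rate, seed = 3)
    cats <- multiplicityCategory(buildCellProfiles(qcFilter(a$contigs)), "IGH")
    mean(cats %in% c("two", "three_or_more"))
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(subsetMix = c(naive = 0.5, memory = 0.5,
                                       plasma = 0.5)), "subsetMix")
  expect_error(simConfig(doubletRate = 0.9), "doubletRate")
  expect_error(simConfig(patternRates = list(IGH = c(0.5, 0.2, 0.1),
                                             IGK = c(1, 0, 0),
                                             IGL = c(1, 0, 0))),
               "patternRates")
  expect_error(simConfig(nCells = 0), "nCells")
})
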