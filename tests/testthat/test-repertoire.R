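test_that("QC presets gate contigs as configured", {
  df <- rbind(
    contigRows("bc1", productive = TRUE, contig_id = "p1"),
    contigRows("bc1", productive = FALSE, contig_id = "p2"),
    contigRows("bc2", full_length = FALSE, v_call = "IGHV9-9",
               contig_id = "p3")
  )
  tab <- ContigTable(df)
  def <- qcFilter(tab, preset = "default")
  expect_identical(length(def), 1L)                    # non-productive out
  vseg <- qcFilter(tab, preset = "v_segment")
  # partially assembled transcript kept so its V gene still counts
  expect_true("p3" %in% contigData(vseg)$contig_id)
  expect_false("p3" %in% contigData(def)$contig_id)
  allPass <- ContigTable(contigRows(c("a", "b"), contig_id = c("x", "y")))
  expect_identical(as.data.frame(contigData(qcFilter(allPass))),
                   as.data.frame(contigData(allPass)))
  floor2 <- qcFilter(ContigTable(contigRows("a", umis = c(1L, 3L),
                                            contig_id = c("u1", "u2"))),
                     umiFloor = 2)
  expect_identical(contigData(floor2)$contig_id, "u2")
})

test_that("identical contigs dedup to one pattern; distinct combinations stay distinct", {
  df <- rbind(
    contigRows("bc1", v_call = "IGHV1-1", d_call = "IGHD1-1",
               cdr3_nt = "GCTAAA", contig_id = c("a1", "a2")),
    contigRows("bc2", v_call = c("IGHV1-8", "IGHV3-23", "IGHV4-34"),
               d_call = "IGHD2-2",
               cdr3_nt = c("GCTAAA", "GCCAAA", "TTTAAA"),
               contig_id = c("b1", "b2", "b3"))
  )
  prof <- buildCellProfiles(ContigTable(df))
  expect_identical(unname(lengths(patternsByLocus(prof, "IGH"))), c(1L, 3L))
})

test_that("per-cell dedup matches an independent brute-force oracle in all key modes", {
  for (seed in 1:20) {
    tab <- randomContigTable(seed)
    df <- as.data.frame(contigData(tab))
    for (mode in c("gene_only", "gene_cdr3nt", "gene_cdr3aa")) {
      prof <- buildCellProfiles(tab, keyMode = mode)
      for (locus in c("IGH", "IGK", "IGL")) {
        got <- lengths(patternsByLocus(prof, locus))
        want <- brutePatternCounts(df, locus, mode)
        expect_identical(unname(got[names(want)]), unname(want),
                         label = sprintf("seed %d %s %s", seed, mode, locus))
        expect_true(all(got[setdiff(names(got), names(want))] == 0L))
      }
    }
  }
})

test_that("coarser keys never yield more patterns per cell", {
  for (seed in 21:30) {
    tab <- randomContigTable(seed)
    nGene <- lengths(patternsByLocus(buildCellProfiles(tab, "gene_only"), "IGH"))
    nAa <- lengths(patternsByLocus(buildCellProfiles(tab, "gene_cdr3aa"), "IGH"))
    nNt <- lengths(patternsByLocus(buildCellProfiles(tab, "gene_cdr3nt"), "IGH"))
    expect_true(all(nGene <= nAa))
    expect_true(all(nAa <= nNt))
  }
})

test_that("multiplicity bins cells as zero/one/two/three_or_more", {
  df <- rbind(
    contigRows("k1", locus = "IGK", v_call = "IGKV1-5", j_call = "IGKJ1",
               contig_id = "k1c"),
    contigRows("m2", v_call = c("IGHV1-1", "IGHV2-5"),
               cdr3_nt = c("GCTAAA", "GCCTTT"), contig_id = c("m2a", "m2b")),
    contigRows("m7", v_call = paste0("IGHV", 1:7, "-1"),
               cdr3_nt = "GCTAAA", contig_id = paste0("m7", letters[1:7]))
  )
  prof <- buildCellProfiles(ContigTable(df))
  cats <- multiplicityCategory(prof, "IGH")
  names(cats) <- barcodes(prof)
  expect_identical(as.character(cats[c("k1", "m2", "m7")]),
                   c("zero", "two", "three_or_more"))
})

test_that("light-chain usage reflects kappa/lambda pattern sets", {
  df <- rbind(
    contigRows("ko", locus = "IGK", v_call = "IGKV1-5", j_call = "IGKJ1",
               contig_id = "koc"),
    contigRows("both", locus = c("IGK", "IGL"),
               v_call = c("IGKV1-5", "IGLV2-14"),
               j_call = c("IGKJ1", "IGLJ2"), contig_id = c("bo1", "bo2")),
    contigRows("none", locus = "IGH", contig_id = "noc")
  )
  u <- lightChainUsage(buildCellProfiles(ContigTable(df)))
  names(u) <- barcodes(buildCellProfiles(ContigTable(df)))
  expect_identical(as.character(u[c("ko", "both", "none")]),
                   c("kappa_only", "both", "none"))
})

test_that("V-segment multiplicity is gene-level and counts partial assemblies", {
  df <- rbind(
    contigRows("bc1", v_call = c("IGHV1-69", "IGHV1-69", "IGHV3-23"),
               j_call = c("IGHJ4", NA, NA),
               full_length = c(TRUE, FALSE, FALSE),
               contig_id = paste0("v", 1:3))
  )
  tab <- ContigTable(df)
  profV <- buildCellProfiles(qcFilter(tab, preset = "v_segment"))
  expect_identical(vSegmentMultiplicity(profV, "IGH"), 2L)
  expect_identical(vSegmentMultiplicity(profV, "IGK"), 0L)
  # bound: at least as many V genes as among full-length patterns
  profDef <- buildCellProfiles(qcFilter(tab, preset = "default"))
  nFull <- length(unique(polyBCR:::parsePatternKeys(
    unlist(patternsByLocus(profDef, "IGH")))$v))
  expect_gte(vSegmentMultiplicity(profV, "IGH"), nFull)
})

test_that("cohort summaries partition denominators exactly", {
  for (seed in c(31, 32, 33)) {
    tab <- randomContigTable(seed)
    prof <- buildCellProfiles(tab)
    s <- summarizeCohort(prof)
    for (m in unique(s$metric)) {
      sm <- s[s$metric == m, ]
      expect_identical(sum(sm$numerator), sm$denominator[1])
      if (sm$denominator[1] > 0)
        expect_lt(abs(sum(sm$proportion) - 1), 1e-12)
    }
  }
})

test_that("cohort summaries reproduce printed numerator/denominator ratios", {
  # 5803 cells with >=1 IGHV, 2886 of them with >=2 distinct IGHV genes
  tab <- vMultiplicityTable("IGH", 5803L, 2886L)
  prof <- buildCellProfiles(qcFilter(tab, preset = "v_segment"))
  s <- summarizeCohort(prof, metrics = "v_multiplicity", loci = "IGH")
  multi <- s[s$category == "multiple", ]
  expect_identical(multi$numerator, 2886L)
  expect_identical(multi$denominator, 5803L)
  expect_identical(round(100 * multi$proportion, 2), 49.73)

  # 41 cells, 31 with >= 2 heavy-chain patterns
  counts <- c(rep(1L, 10), rep(2L, 22), rep(8L, 9))
  df <- do.call(rbind, lapply(seq_along(counts), function(i)
    contigRows(sprintf("sc%02d", i),
               v_call = paste0("IGHV", seq_len(counts[i]), "-1"),
               cdr3_nt = "GCTAAA",
               contig_id = sprintf("sc%02d_%d", i, seq_len(counts[i])))))
  s2 <- summarizeCohort(buildCellProfiles(ContigTable(df)),
                        metrics = "multiplicity", loci = "IGH")
  multi2 <- sum(s2$numerator[s2$category %in% c("two", "three_or_more")])
  expect_identical(multi2, 31L)
  expect_identical(round(100 * multi2 / s2$denominator[1], 2), 75.61)

  # one cell, one pattern
  one <- summarizeCohort(
    buildCellProfiles(ContigTable(contigRows("solo", contig_id = "s1"))),
    metrics = "multiplicity", loci = "IGH")
  expect_identical(one$proportion[one$category == "one"], 1)
})

test_that("summaries are deterministic for identical inputs", {
  t1 <- randomContigTable(44)
  t2 <- randomContigTable(44)
  s1 <- summarizeCohort(buildCellProfiles(t1))
  s2 <- summarizeCohort(buildCellProfiles(t2))
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
})

test_that("grouped summaries split denominators by group", {
  tab <- randomContigTable(55)
  prof <- buildCellProfiles(tab)
  grp <- rep(c("d1", "d2"), length.out = nCells(prof))
  s <- summarizeCohort(prof, groupBy = grp, metrics = "multiplicity",
                       loci = "IGH")
  whole <- summarizeCohort(prof, metrics = "multiplicity", loci = "IGH")
  expect_identical(sum(s$numerator), sum(whole$numerator))
  expect_setequal(unique(s$group), c("d1", "d2"))
})
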