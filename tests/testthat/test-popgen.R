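test_that("allele frequencies count both copies and skip missing calls", {
  gm <- makeGM(list(list(c("A", "A")), list(c("A", "B")), list(NA)),
               loci = "L1")
  af <- alleleFrequencies(gm, "L1")
  expect_equal(af$freq[af$allele == "A"], 0.75)
  expect_equal(af$freq[af$allele == "B"], 0.25)
  expect_equal(attr(af, "n_typed"), 2L)

  mono <- makeGM(rep(list(list(c("A", "A"))), 5), loci = "L1")
  afm <- alleleFrequencies(mono, "L1")
  expect_equal(afm$freq, 1)
  expect_equal(nrow(afm), 1L)

  allMiss <- makeGM(list(list(NA), list(NA)), loci = "L1")
  expect_error(alleleFrequencies(allMiss, "L1"), "no non-missing")

  # large random matrix against an independent tally
  cfg <- simulationConfig(nLoci = 1, alleleCounts = 6, nIsolinePairs = 0)
  pan <- simulatePanel(cfg, 71)
  big <- simulateGenotypes(pan, cfg, 500, 72)
  af2 <- alleleFrequencies(big, 1)
  tally <- table(c(big@alleleA[, 1], big@alleleB[, 1]))
  expect_equal(setNames(af2$count, af2$allele),
               setNames(as.integer(tally), names(tally))[af2$allele])
  expect_equal(sum(af2$freq), 1, tolerance = 1e-12)
})

test_that("locus summaries reproduce closed-form He and PIC", {
  # p = (0.5, 0.5): He = 0.5, PIC = 0.375
  gm <- makeGM(list(list(c("A", "A")), list(c("B", "B")),
                    list(c("A", "B")), list(c("A", "B"))), loci = "L1")
  ls <- locusSummary(gm, "L1")
  expect_equal(ls$He, 0.5)
  expect_equal(ls$PIC, 0.375)
  expect_equal(ls$Ho, 0.5)
  expect_equal(ls$k, 2L)

  # monomorphic locus: everything collapses to zero
  mono <- makeGM(rep(list(list(c("A", "A"))), 4), loci = "L1")
  lsm <- locusSummary(mono, "L1")
  expect_equal(c(lsm$He, lsm$PIC, lsm$Ho), c(0, 0, 0))
  expect_equal(lsm$k, 1L)

  # p = (0.5, 0.25, 0.25) by direct construction: 8 allele copies
  gm3 <- makeGM(list(list(c("A", "A")), list(c("A", "B")),
                     list(c("A", "C")), list(c("B", "C"))), loci = "L1")
  expect_equal(locusSummary(gm3, "L1")$PIC, 0.5546875)
  expect_equal(locusSummary(gm3, "L1")$PIC, picOracle(c(0.5, 0.25, 0.25)))
})

test_that("PIC <= He on random frequency vectors, both zero iff k = 1", {
  set.seed(99)
  for (i in seq_len(300)) {
    k <- sample(1:8, 1)
    p <- rgamma(k, 1)
    p <- p / sum(p)
    he <- 1 - sum(p^2)
    pic <- picOracle(p)
    impl <- PapaverSSR:::picFromFreq(p)
    expect_equal(impl, pic, tolerance = 1e-12)
    expect_lte(impl, he + 1e-12)
    if (k == 1) expect_equal(c(impl, he), c(0, 0))
  }
})

test_that("published per-locus allele counts summarise to the printed rows", {
  k <- opestAlleleCounts()
  sAll <- panelSummary(k["k_all"])
  expect_equal(sAll[sAll$statistic == "total", "k_all"], 118)
  expect_equal(round(sAll[sAll$statistic == "mean", "k_all"], 2), 6.94)
  expect_equal(sAll[sAll$statistic == "median", "k_all"], 7)
  expect_equal(sAll[sAll$statistic == "min", "k_all"], 3)
  expect_equal(sAll[sAll$statistic == "max", "k_all"], 10)

  sSom <- panelSummary(k["k_somniferum"])
  expect_equal(sSom[sSom$statistic == "total", "k_somniferum"], 88)
  expect_equal(round(sSom[sSom$statistic == "mean", "k_somniferum"], 2),
               5.18)
  expect_equal(sSom[sSom$statistic == "median", "k_somniferum"], 5)

  sCul <- panelSummary(k["k_culinary"])
  expect_equal(sCul[sCul$statistic == "total", "k_culinary"], 77)
  expect_equal(round(sCul[sCul$statistic == "mean", "k_culinary"], 2), 4.53)
  expect_equal(sCul[sCul$statistic == "median", "k_culinary"], 4)
})

test_that("groupReport emits per-group rows plus summary statistics", {
  cfg <- simulationConfig(nLoci = 5, alleleCounts = c(4, 3, 5, 2, 6),
                          nIsolinePairs = 0)
  gm <- simulateGenotypes(simulatePanel(cfg, 3), cfg, 30, 4)
  rep_ <- groupReport(gm)
  # default groups: all, the species, and the within-species group label
  expect_equal(sort(unique(rep_$perLocus$group)),
               sort(c("all", "P. somniferum", "P. somniferum-culinary")))
  expect_equal(nrow(rep_$perLocus), 5 * 3)
  expect_true(all(c("k", "Ho", "He", "PIC") %in% names(rep_$summary)))
  expect_error(groupReport(gm, list(empty = character())), "empty group")
})

test_that("allele mismatch counts shared copies of unordered pairs", {
  expect_equal(alleleMismatch(c("A", "A"), c("A", "A")), 0L)
  expect_equal(alleleMismatch(c("A", "A"), c("A", "B")), 1L)
  expect_equal(alleleMismatch(c("A", "B"), c("C", "D")), 2L)
  expect_equal(alleleMismatch(c("A", "B"), c("B", "A")), 0L)
  expect_equal(alleleMismatch(c("A", "B"), c("B", "B")), 1L)
  expect_error(alleleMismatch(c("A", NA), c("A", "A")), "non-missing")
})

test_that("identity analysis equals a brute-force all-pairs oracle", {
  cfg <- simulationConfig(nLoci = 17, nIsolinePairs = 2, piHomo = 0.5)
  pan <- simulatePanel(cfg, 55)
  gm <- simulateGenotypes(pan, cfg, 24, 56)
  idr <- identityAnalysis(gm, maxMismatch = 5, minSharedLoci = 10)

  ids <- accessionIds(gm)
  oracleCounts <- integer(6)
  nonUnique <- character()
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in seq.int(i + 1, length(ids))) {
      mm <- 0L
      shared <- 0L
      for (l in lociNames(gm)) {
        c1 <- genotypeCall(gm, i, l)
        c2 <- genotypeCall(gm, j, l)
        if (anyNA(c1) || anyNA(c2)) next
        shared <- shared + 1L
        mm <- mm + alleleMismatch(c1, c2)
      }
      if (shared < 10) next
      for (t in 0:5) if (mm <= t)
        oracleCounts[t + 1] <- oracleCounts[t + 1] + 1L
      if (mm == 0) nonUnique <- union(nonUnique, c(ids[i], ids[j]))
    }
  }
  expect_equal(unname(idr$matchCounts), oracleCounts)
  expect_equal(idr$nUniqueProfiles, length(ids) - length(nonUnique))
  # monotone non-decreasing in the mismatch allowance
  expect_true(all(diff(idr$matchCounts) >= 0))
  # the two isoline pairs match exactly at t = 0
  expect_gte(idr$matchCounts["t0"], 2)
})

test_that("single-allele differences match first at t = 1", {
  gm <- makeGM(list(as.list(rep("150", 17)),
                    c(as.list(rep("150", 16)), list(c("150", "153")))),
               loci = sprintf("L%02d", 1:17))
  idr <- identityAnalysis(gm)
  expect_equal(unname(idr$matchCounts[c("t0", "t1")]), c(0L, 1L))
})

test_that("pairs sharing too few loci are incomparable, not matched", {
  calls1 <- as.list(rep("150", 17))
  calls2 <- c(as.list(rep("150", 5)), rep(list(NA), 12))
  gm <- makeGM(list(calls1, calls2), loci = sprintf("L%02d", 1:17))
  idr <- identityAnalysis(gm, minSharedLoci = 10)
  expect_equal(nrow(idr$pairs), 0L)
  expect_equal(nrow(idr$incomparablePairs), 1L)
  expect_equal(idr$nUniqueProfiles, 2L)
})

test_that("pID matches exhaustive genotype-pair enumeration", {
  expect_equal(pIdentity(list(c(0.5, 0.5)))$pID, 0.375)
  expect_equal(pIdentity(list(c(0.5, 0.5), c(0.5, 0.5)))$pID, 0.140625)
  set.seed(314)
  for (i in seq_len(50)) {
    k <- sample(2:6, 1)
    p <- rgamma(k, 1)
    p <- p / sum(p)
    got <- pIdentity(list(p))
    expect_equal(got$pID, pidEnumeration(p), tolerance = 1e-12)
    expect_gte(got$pIDsib, got$pID)  # sibling variant is always larger
  }
  expect_error(pIdentity(list()), "empty locus set")
})

test_that("pID decreases strictly as polymorphic loci are added", {
  set.seed(15)
  freqs <- lapply(1:6, function(i) {
    p <- rgamma(3, 1)
    p / sum(p)
  })
  vals <- vapply(seq_along(freqs), function(m)
    pIdentity(freqs[seq_len(m)])$pID, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("error rates implement the per-allele and per-locus formulas", {
  loci <- sprintf("L%02d", 1:3)
  base <- lapply(1:10, function(i) as.list(rep("150", 3)))
  ref <- makeGM(base, loci = loci)
  expect_equal(errorRates(ref, ref)$meanEa, 0)
  expect_equal(errorRates(ref, ref)$meanEl, 0)

  # one accession differing at one allele of one locus: e_a = 1/20, e_l = 1/10
  repl <- base
  repl[[1]][[1]] <- c("150", "153")
  er <- errorRates(ref, makeGM(repl, loci = loci))
  expect_equal(er$perLocus$e_a[1], 0.05)
  expect_equal(er$perLocus$e_l[1], 0.10)

  # missing-in-one counts as a full locus failure (m_l += 1, m_a += 2)
  repl2 <- base
  repl2[[1]][[1]] <- NA
  er2 <- errorRates(ref, makeGM(repl2, loci = loci))
  expect_equal(er2$perLocus$m_a[1], 2L)
  expect_equal(er2$perLocus$m_l[1], 1L)
  expect_equal(er2$perLocus$e_a[1], er2$perLocus$e_l[1])

  # missing in both datasets drops out of n entirely
  ref3 <- base
  ref3[[2]][[1]] <- NA
  repl3 <- base
  repl3[[2]][[1]] <- NA
  er3 <- errorRates(makeGM(ref3, loci = loci), makeGM(repl3, loci = loci))
  expect_equal(er3$perLocus$n[1], 9L)

  expect_error(errorRates(ref, makeGM(base, loci = loci,
                                      ids = sprintf("B%02d", 1:10))),
               "share no accession")
})

test_that("the printed per-locus error maximum reconstructs from n = 35", {
  loci <- "L1"
  base <- lapply(1:35, function(i) list(c("150", "150")))
  repl <- base
  repl[[1]][[1]] <- c("153", "156")  # both alleles wrong
  er <- errorRates(makeGM(base, loci = loci), makeGM(repl, loci = loci))
  expect_equal(round(100 * er$perLocus$e_a, 2), 2.86)
  expect_equal(round(100 * er$perLocus$e_l, 2), 2.86)
})

test_that("e_l/2 <= e_a <= e_l holds across random error reports", {
  cfg <- simulationConfig(nIsolinePairs = 0)
  pan <- simulatePanel(cfg, 201)
  gm <- simulateGenotypes(pan, cfg, 60, 202)
  for (s in 1:5) {
    repl <- injectErrors(gm, 0.05, 0.05, 300 + s, pan)
    er <- errorRates(gm, repl)
    ok <- er$perLocus$n > 0
    expect_true(all(er$perLocus$e_a[ok] >= er$perLocus$e_l[ok] / 2 - 1e-12))
    expect_true(all(er$perLocus$e_a[ok] <= er$perLocus$e_l[ok] + 1e-12))
    expect_true(all(er$perLocus$e_a[ok] >= 0 & er$perLocus$e_l[ok] <= 1))
  }
})

test_that("transferability summary applies the AND rule and percentages", {
  tm <- referenceTransferability()
  congeners <- c("P. nudicaule", "P. orientale", "P. glaucum", "P. rhoeas")
  ts <- transferabilitySummary(tm, congeners)
  expect_equal(unname(ts$perSpecies[congeners]), c(13, 10, 9, 8))
  expect_equal(unname(ts$perSpecies["A. mexicana"]), 2)
  expect_equal(ts$pctAllFocal, 29.41)
  expect_equal(ts$pctAllButOneFocal, 41.18)
  expect_equal(ts$pctAtLeastOneFocal, 88.24)
  expect_equal(ts$pctCrossGenera, 11.76)

  # a marker present in one lab only is absent from the consensus
  amp <- array(TRUE, dim = c(1, 1, 2),
               dimnames = list("m1", "spA", c("lab1", "lab2")))
  amp[1, 1, 2] <- FALSE
  expect_false(consensusAmplification(TransferabilityMatrix(amp))[1, 1])
})

test_that("marker QC flags multipeak, low polymorphism, implausible Ho", {
  loci <- c("kLow", "hetHigh", "clean")
  calls <- lapply(1:20, function(i) {
    list(c("150", "150"),               # k = 2 overall, see below
         c("150", "153"),               # every accession heterozygous
         c(as.character(150 + 3 * (i %% 5)), as.character(150 + 3 * (i %% 5))))
  })
  calls[[1]][[1]] <- c("153", "153")    # second allele for kLow -> k = 2
  gm <- makeGM(calls, loci = loci)
  qc <- markerQC(gm, minAlleles = 3, maxHetFraction = 0.5)
  expect_equal(qc$reasons[qc$locus == "kLow"], "LOW_POLYMORPHISM")
  expect_match(qc$reasons[qc$locus == "hetHigh"], "IMPLAUSIBLE_HET")
  expect_true(qc$pass[qc$locus == "clean"])

  peaks <- data.frame(accession = "a1", locus = "clean", lab = "DGB",
                      stringsAsFactors = FALSE)
  peaks$sizes <- list(c(150, 153, 156))
  qc2 <- markerQC(gm, peaks = peaks)
  expect_match(qc2$reasons[qc2$locus == "clean"], "MULTIPEAK")
})
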