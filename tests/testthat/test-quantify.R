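# two groups G1, G2 sharing peptide "c"; unique evidence 4 vs 1
.twoGroupPSMs <- function(nShared = 10, nU1 = 4, nU2 = 1) {
  rbind(psmRows("a", nU1), psmRows("d", nU2), psmRows("c", nShared))
}

.twoGroupSet <- function() {
  inferMinimalSet(new("PeptideProteinMap",
                      map = list(a = "G1", c = c("G1", "G2"), d = "G2"),
                      orphans = character(0)))
}

test_that("spectral counting assigns each PSM exactly once", {
  g <- .twoGroupSet()
  psms <- .twoGroupPSMs()
  ct <- countSpectra(psms, g)
  expect_equal(ct$rawUnique["G1", "F1.1"], 4)
  expect_equal(ct$rawUnique["G2", "F1.1"], 1)
  expect_equal(ct$sharedCounts$count, 10)
  expect_equal(sum(ct$rawUnique) + sum(ct$sharedCounts$count),
               nrow(psms))
  # order invariance
  set.seed(1)
  ct2 <- countSpectra(psms[sample(nrow(psms)), ], g)
  expect_identical(ct, ct2)
  # unclassified peptides are a hard error
  expect_error(countSpectra(psmRows("zz", 1), g), "zz")
})

test_that("shared spectra are apportioned by unique evidence", {
  g <- .twoGroupSet()
  ap <- apportionShared(countSpectra(.twoGroupPSMs(), g))
  # u = (4, 1), s = 10 -> allocations (8, 2); totals include unique
  expect_equal(ap["G1", "F1.1"], 4 + 8)
  expect_equal(ap["G2", "F1.1"], 1 + 2)
  # zero unique evidence: s = 6 splits equally
  psms0 <- psmRows("c", 6)
  ap0 <- apportionShared(countSpectra(psms0, g))
  expect_equal(unname(ap0[, "F1.1"]), c(3, 3))
})

test_that("apportionment conserves counts exactly and matches a per-peptide oracle", {
  set.seed(7)
  for (i in 1:10) {
    gp <- generateProteome(12, nFamilies = 2, seed = i)
    plant <- plantedAbundance(names(gp$proteins), nEnriched = 4,
                              nReference = 4, nFlat = 4, seed = i)
    tabs <- generatePSMTables(gp, fractionDesign(plant$abundance,
                                                 replicates = 2,
                                                 depth = 500, seed = i))
    psms <- do.call(rbind, tabs)
    m <- mapPeptides(unique(psms$peptide),
                     as.character(gp$proteins))
    g <- inferMinimalSet(m)
    ct <- countSpectra(psms, g)
    ap <- apportionShared(ct)
    # conservation per sample at full floating precision
    perSample <- table(paste(psms$sample, psms$replicate, sep = "."))
    expect_equal(unname(colSums(ap)[names(perSample)]),
                 as.numeric(perSample), tolerance = 1e-12)
    # independent per-peptide recomputation of the whole matrix
    oracle <- ct$rawUnique + 0
    for (r in seq_len(nrow(ct$sharedCounts))) {
      gs <- ct$classification[[ct$sharedCounts$peptide[r]]]
      u <- ct$rawUnique[gs, ct$sharedCounts$sample[r]]
      s <- ct$sharedCounts$count[r]
      want <- if (sum(u) > 0) s * u / sum(u) else rep(s / length(gs),
                                                      length(gs))
      oracle[gs, ct$sharedCounts$sample[r]] <-
        oracle[gs, ct$sharedCounts$sample[r]] + want
    }
    expect_equal(ap, oracle, tolerance = 1e-9)
  }
})

test_that("single shared peptide allocations equal the closed formula", {
  g <- .twoGroupSet()
  set.seed(3)
  for (i in 1:20) {
    nU1 <- sample(0:6, 1); nU2 <- sample(0:6, 1); s <- sample(1:20, 1)
    ct <- countSpectra(.twoGroupPSMs(s, max(nU1, 0), max(nU2, 0)), g)
    ap <- apportionShared(ct)
    u <- c(nU1, nU2)
    want <- if (sum(u) > 0) s * u / sum(u) else c(s / 2, s / 2)
    expect_equal(unname(ap[, "F1.1"] - ct$rawUnique[, "F1.1"]), want,
                 tolerance = 1e-12)
    expect_equal(sum(ap), nU1 + nU2 + s, tolerance = 1e-12)
  }
})

test_that("apportionment by distinct unique peptides is available", {
  # G1 has 2 distinct unique peptides but 2 spectra; G2 has 1 and 6
  g <- inferMinimalSet(new("PeptideProteinMap",
                           map = list(a = "G1", b = "G1",
                                      c = c("G1", "G2"), d = "G2"),
                           orphans = character(0)))
  psms <- rbind(psmRows("a", 1), psmRows("b", 1), psmRows("d", 6),
                psmRows("c", 9))
  ct <- countSpectra(psms, g)
  bySpec <- apportionShared(ct, method = "spectra")
  byPep <- apportionShared(ct, method = "peptides")
  expect_equal(unname(bySpec[, 1] - ct$rawUnique[, 1]),
               9 * c(2, 6) / 8)
  expect_equal(unname(byPep[, 1] - ct$rawUnique[, 1]),
               9 * c(2, 1) / 3)
})

test_that("percent normalization and scale invariance hold", {
  ap <- matrix(c(30, 70, 2, 8), 2,
               dimnames = list(c("A", "B"), c("s1", "s2")))
  pc <- percentTotal(ap)
  expect_equal(unname(pc[, "s1"]), c(30, 70))
  expect_equal(colSums(pc), c(s1 = 100, s2 = 100), tolerance = 1e-9)
  expect_equal(percentTotal(2 * ap), pc)
  expect_error(percentTotal(cbind(ap, bad = c(0, 0))), "bad")
})

test_that("replicate averaging uses mean and n-1 standard deviation", {
  pc <- matrix(c(10, 90, 20, 80, 30, 70), 2,
               dimnames = list(c("A", "B"),
                               c("F.1", "F.2", "F.3")))
  samples <- data.frame(sample = rep("F", 3), replicate = 1:3)
  prof <- averageReplicates(pc, samples)
  expect_equal(unname(prof$mean[, "F"]), c(20, 80))
  expect_equal(unname(prof$sd[, "F"]), c(10, 10))
  one <- averageReplicates(pc[, 1, drop = FALSE],
                           samples[1, , drop = FALSE])
  expect_equal(unname(one$sd[, "F"]), c(0, 0))
})

test_that("the assembled FractionQuant satisfies its invariants", {
  gp <- generateProteome(15, nFamilies = 2, seed = 8)
  plant <- plantedAbundance(names(gp$proteins), nEnriched = 5,
                            nReference = 5, nFlat = 5, seed = 8)
  psms <- do.call(rbind, generatePSMTables(
    gp, fractionDesign(plant$abundance, replicates = 3, depth = 1000,
                       seed = 8)))
  g <- inferMinimalSet(mapPeptides(unique(psms$peptide),
                                   as.character(gp$proteins)))
  fq <- quantifySpectra(psms, g)
  expect_s4_class(fq, "FractionQuant")
  ap <- SummarizedExperiment::assay(fq, "apportioned")
  tot <- table(paste0(psms$sample, ".", psms$replicate))
  expect_equal(colSums(ap)[names(tot)],
               stats::setNames(as.numeric(tot), names(tot)))
  prof <- fractionProfile(fq)
  pc <- SummarizedExperiment::assay(fq, "percent")
  cd <- SummarizedExperiment::colData(fq)
  for (f in unique(cd$fraction)) {
    cols <- which(cd$fraction == f)
    expect_equal(unname(prof$mean[, f]),
                 unname(rowMeans(pc[, cols, drop = FALSE])))
  }
})
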