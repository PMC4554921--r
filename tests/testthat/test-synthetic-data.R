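test_that("tryptic digest cleaves after K/R except before P", {
  expect_equal(digestSequence("AAKBBRCC", minLen = 2, maxLen = 10),
               c("AAK", "BBR", "CC"))
  expect_equal(digestSequence("AAKPBB", minLen = 2, maxLen = 10),
               "AAKPBB")
  expect_equal(digestSequence("KAK", minLen = 1, maxLen = 10),
               c("K", "AK"))
  expect_error(digestSequence("AAk"), "invalid residue")
  expect_error(digestSequence(""), "non-empty")
})

test_that("unfiltered digest partitions the sequence", {
  set.seed(11)
  for (i in 1:10) {
    s <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 200,
                      replace = TRUE), collapse = "")
    peps <- digestSequence(s, minLen = 1, maxLen = .Machine$integer.max)
    expect_identical(paste(peps, collapse = ""), s)
  }
})

test_that("proteome generation is deterministic and family-structured", {
  g1 <- generateProteome(12, nFamilies = 2, seed = 1)
  g2 <- generateProteome(12, nFamilies = 2, seed = 1)
  expect_identical(as.character(g1$proteins), as.character(g2$proteins))
  expect_identical(g1$peptideMap, g2$peptideMap)
  expect_length(g1$proteins, 12)
  # every family accession exists; some peptide is shared by >= 2
  # proteins and some protein retains a unique peptide
  expect_true(all(unlist(g1$families) %in% names(g1$proteins)))
  expect_true(any(lengths(g1$peptideMap) >= 2))
  expect_true(any(lengths(g1$peptideMap) == 1))
  expect_error(generateProteome(1), "nProteins")
})

test_that("generated peptide map equals an exhaustive substring oracle", {
  gp <- generateProteome(50, nFamilies = 5, seed = 7)
  seqs <- as.character(gp$proteins)
  for (p in names(gp$peptideMap)) {
    oracle <- names(seqs)[vapply(seqs, function(s)
      grepl(p, s, fixed = TRUE), logical(1))]
    expect_identical(gp$peptideMap[[p]], oracle)
  }
})

test_that("a strict sequence prefix shares all of its peptides", {
  gp <- generateProteome(6, nFamilies = 0, seed = 3)
  full <- as.character(gp$proteins)[[1]]
  segs <- digestSequence(full, 1, .Machine$integer.max)
  pre <- paste(segs[1:4], collapse = "")
  m <- peptideMap(mapPeptides(digestSequence(pre, 6, 30),
                              c(FULL = full, PRE = pre)))
  expect_true(all(vapply(m, function(v) all(c("FULL", "PRE") %in% v),
                         logical(1))))
})

test_that("PSM sampling follows the design and conserves totals", {
  gp <- generateProteome(6, nFamilies = 0, seed = 5)
  acc <- names(gp$proteins)
  # degenerate design: one protein takes everything
  ab <- matrix(c(1, rep(0, 5)), ncol = 1,
               dimnames = list(acc, "OnlyF"))
  tabs <- generatePSMTables(gp, fractionDesign(ab, replicates = 1,
                                               depth = 100, seed = 2))
  tab <- tabs[[1]]
  own <- digestSequence(as.character(gp$proteins)[[1]], 6, 30)
  expect_true(all(tab$peptide %in% own))
  expect_true(all(tab$confidence >= 0.95))
  # two proteins 0.9 / 0.1: observed share within 3 binomial s.e.
  ab2 <- matrix(c(0.9, 0.1, rep(0, 4)), ncol = 1,
                dimnames = list(acc, "F"))
  t2 <- generatePSMTables(gp, fractionDesign(ab2, replicates = 1,
                                             depth = 10000, seed = 4))[[1]]
  p1 <- digestSequence(as.character(gp$proteins)[[1]], 6, 30)
  share <- mean(t2$peptide %in% p1)
  se <- sqrt(0.9 * 0.1 / nrow(t2))
  expect_lt(abs(share - 0.9), 3 * se)
  # determinism: byte-identical tables on rerun
  t3 <- generatePSMTables(gp, fractionDesign(ab2, replicates = 1,
                                             depth = 10000, seed = 4))[[1]]
  expect_identical(t2, t3)
})

test_that("PSM generation refuses proteins with no usable peptides", {
  gp <- generateProteome(4, nFamilies = 0, seed = 5)
  gp$proteins <- Biostrings::AAStringSet(
    c(stats::setNames(as.character(gp$proteins), names(gp$proteins)),
      BARE = "AKCKDKEK"))
  ab <- matrix(c(0.5, 0, 0, 0, 0.5), ncol = 1,
               dimnames = list(names(gp$proteins), "F"))
  expect_error(generatePSMTables(gp, fractionDesign(ab, 1, 100, 1)),
               "BARE")
})

test_that("gold scenes place particles on structures with known labels", {
  d0 <- goldDesign(c(plasma_membrane = 1, cisternae = 0, flagellum = 0),
                   nParticles = 50, nMicrographs = 2, jitterSd = 0,
                   controlFraction = 0, seed = 9)
  for (sc in generateGoldScenes(d0)) {
    pm <- Filter(function(s) s$compartment == "plasma_membrane",
                 sceneStructures(sc))[[1]]
    p <- sceneParticles(sc)
    d <- abs(distanceToStructure(cbind(p$x, p$y), pm))
    expect_true(all(d < 1e-9))
    expect_true(all(p$truth == "plasma_membrane"))
  }
  # multinomial proportions recovered within 3 s.e. at scale
  frac <- c(plasma_membrane = 0.55, cisternae = 0.40, flagellum = 0.05)
  dd <- goldDesign(frac, nParticles = 300, nMicrographs = 20,
                   jitterSd = 0, controlFraction = 0, seed = 3)
  lab <- unlist(lapply(generateGoldScenes(dd),
                       function(s) sceneParticles(s)$truth))
  n <- length(lab)
  for (cmp in names(frac)) {
    se <- sqrt(frac[[cmp]] * (1 - frac[[cmp]]) / n)
    expect_lt(abs(mean(lab == cmp) - frac[[cmp]]), 3 * se)
  }
})

test_that("control scenes carry only background particles", {
  d <- goldDesign(c(plasma_membrane = 0.5, cisternae = 0.4,
                    flagellum = 0.1),
                  nParticles = 100, nMicrographs = 10, jitterSd = 5,
                  controlFraction = 0.3, backgroundMax = 4, seed = 6)
  scenes <- generateGoldScenes(d)
  ctrl <- Filter(isControl, scenes)
  expect_length(ctrl, 3)
  expect_true(all(vapply(ctrl, function(s) nrow(sceneParticles(s)),
                         integer(1)) <= 4))
  expect_true(all(vapply(ctrl,
                         function(s) all(is.na(sceneParticles(s)$truth)),
                         logical(1))))
})

test_that("seed streams make stages independently reproducible", {
  expect_identical(childSeed(1, "a"), childSeed(1, "a"))
  expect_false(childSeed(1, "a") == childSeed(1, "b"))
  expect_false(childSeed(1, "a") == childSeed(2, "a"))
  expect_true(childSeed(2147483646, "long key with text") >= 0)
})
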