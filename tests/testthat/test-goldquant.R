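test_that("point-to-polyline distances match the segment-wise oracle", {
  # simple exact cases
  horiz <- list(coords = rbind(c(0, 0), c(100, 0)), closed = FALSE)
  expect_equal(distanceToStructure(c(0, 0), horiz), 0)
  expect_equal(distanceToStructure(c(50, 30), horiz), 30)
  expect_equal(distanceToStructure(c(-40, 0), horiz), 40)  # beyond end
  # signed distance for a closed square: negative inside
  sq <- list(coords = rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100)),
             closed = TRUE)
  expect_equal(distanceToStructure(c(50, 50), sq), -50)
  expect_equal(distanceToStructure(c(150, 50), sq), 50)
  expect_error(distanceToStructure(c(1, 1),
                                   list(coords = rbind(c(5, 5), c(5, 5)),
                                        closed = FALSE)),
               "degenerate")
  # 200 random points vs a random polyline
  set.seed(12)
  poly <- list(coords = cbind(cumsum(runif(8, -50, 80)),
                              cumsum(runif(8, -60, 60))),
               closed = FALSE)
  pts <- cbind(runif(200, -100, 400), runif(200, -200, 200))
  got <- distanceToStructure(pts, poly)
  for (i in 1:200)
    expect_lt(abs(got[i] - bruteSegmentDistance(pts[i, ], poly$coords)),
              1e-9)
})

test_that("band histogram uses half-open bins at increment multiples", {
  # particles at signed distances -5, 12, 0, 35.9, -12 from the top edge
  # of the square membrane (y = 0 side): place on a big square so the
  # nearest membrane point is that edge
  sc <- simpleScene(particleFrame(c(500, 500, 500, 500, 500),
                                  c(5, -12, 0, -35.9, 12)))
  h <- bandHistogram(sc, increment = 12)
  expect_equal(sum(h$bins), 5)
  # signed distances: -5, +12, 0, +35.9, -12
  expect_equal(unname(h$bins[["-12"]]), 2)  # -5 and exactly -12
  expect_equal(unname(h$bins[["0"]]), 1)    # the on-membrane particle
  expect_equal(unname(h$bins[["12"]]), 1)
  expect_equal(unname(h$bins[["24"]]), 1)   # 35.9 in [24, 36)
  expect_equal(h$nScored, 5)
})

test_that("band histogram bin edges: exact multiples fall in the upper bin", {
  sc <- simpleScene(particleFrame(c(500, 500), c(-12, -24)))
  # outside the membrane (negative y): signed distances +12 and +24
  h <- bandHistogram(sc, increment = 12)
  expect_equal(unname(h$bins[["12"]]), 1)
  expect_equal(unname(h$bins[["24"]]), 1)
  expect_equal(unname(h$bins[["0"]]), 0)
})

test_that("reference band is the smallest covering symmetric span", {
  sc <- simpleScene(particleFrame(rep(500, 7), c(2, 5, -8, 9, 3, 1, 8)))
  h <- bandHistogram(sc, increment = 12)
  expect_equal(referenceBand(h), 12)  # all within +/- 10 nm
  set.seed(4)
  scU <- simpleScene(particleFrame(rep(500, 400), runif(400, -35.9, 35.9)))
  expect_equal(referenceBand(bandHistogram(scU, increment = 12)), 36)
  # Gaussian offsets: result equals exhaustive span search
  y <- rnorm(500, 0, 15)
  scG <- simpleScene(particleFrame(rep(500, 500), y))
  hG <- bandHistogram(scG, increment = 12)
  d <- -y[abs(y) <= 120]  # signed distance = -y for the y=0 edge top
  oracle <- NA
  for (k in 1:10) {
    if (sum(d >= -12 * k & d < 12 * k) >= 0.95 * length(d)) {
      oracle <- 12 * k; break
    }
  }
  expect_equal(referenceBand(hG, coverage = 0.95), oracle)
  expect_error(referenceBand(bandHistogram(simpleScene(
    particleFrame(numeric(0), numeric(0))))), "empty")
})

test_that("particles are classified by nearest structure within band", {
  sc <- simpleScene(particleFrame(
    x = c(500, 500, 500, 2200, 500, 500, 1500),
    y = c(30, 470, 490, 390, 700, -50, 500)))
  cls <- classifyParticles(sc, bandHalfWidth = 36)
  expect_identical(cls$zone[1], "plasma_membrane_cross")  # 30 nm from PM
  expect_identical(cls$zone[2], "intracytoplasmic")       # 30 nm from cis
  expect_identical(cls$zone[3], "intracytoplasmic")       # 10 nm from cis
  expect_identical(cls$zone[4], "flagellum_oblique")      # 10 nm from fl
  expect_identical(cls$zone[5], "intracytoplasmic")       # inside, no band
  expect_identical(cls$zone[6], "unassigned")             # outside, 50 nm
  expect_identical(cls$compartment[6], "unassigned")
  # ties between plasma membrane and another structure favour the membrane
  tie <- simpleScene(particleFrame(500, 250))  # 250 from PM top, 250 cis
  expect_identical(classifyParticles(tie, bandHalfWidth = 300)$zone,
                   "plasma_membrane_cross")
})

test_that("jitter-free scenes classify with full truth agreement", {
  d <- goldDesign(c(plasma_membrane = 0.5, cisternae = 0.4,
                    flagellum = 0.1),
                  nParticles = 200, nMicrographs = 4, jitterSd = 0,
                  controlFraction = 0, seed = 2)
  for (sc in generateGoldScenes(d)) {
    cls <- classifyParticles(sc, bandHalfWidth = 36)
    expect_identical(cls$compartment, cls$truth)
  }
})

test_that("zone distributions pool, normalize and separate controls", {
  p1 <- particleFrame(c(rep(500, 10), rep(500, 10)),
                      c(rep(5, 10), rep(500, 10)))
  sc1 <- simpleScene(p1, sceneId = "a", dilution = "1:5")
  zd <- zoneDistribution(list(sc1), bandHalfWidth = 36)
  s <- zd$summary
  expect_equal(s$meanPercent[s$compartment == "plasma_membrane"], 50)
  expect_equal(s$meanPercent[s$compartment ==
                               "intracytoplasmic_cisternae"], 50)
  expect_equal(s$meanPercent[s$compartment == "flagellum"], 0)
  expect_equal(sum(s$meanPercent), 100, tolerance = 1e-9)
  # per-unit percentages always sum to 100
  sc2 <- simpleScene(particleFrame(rep(2200, 8), rep(390, 8)),
                     sceneId = "b", dilution = "1:10")
  ctrl <- simpleScene(particleFrame(100, 100), sceneId = "c",
                      dilution = "1:5", isControl = TRUE)
  zd2 <- zoneDistribution(list(sc1, sc2, ctrl), bandHalfWidth = 36)
  for (u in unique(zd2$perUnit$unit))
    expect_equal(sum(zd2$perUnit$percent[zd2$perUnit$unit == u]), 100,
                 tolerance = 1e-9)
  expect_equal(zd2$summary$nUnits[1], 2)
  expect_identical(zd2$controls$sceneId, "c")
  expect_equal(zd2$nParticles, 28)  # controls never pooled
  expect_error(zoneDistribution(list(ctrl)), "non-control")
})

test_that("zonal composition recovers generating fractions within sampling error", {
  frac <- c(plasma_membrane = 0.21, cisternae = 0.67, flagellum = 0.12)
  d <- goldDesign(frac, nParticles = 250, nMicrographs = 6,
                  jitterSd = 10, controlFraction = 0, seed = 5)
  zd <- zoneDistribution(generateGoldScenes(d), bandHalfWidth = 36)
  pooled <- tapply(zd$perUnit$count, zd$perUnit$compartment, sum)
  n <- sum(pooled)
  want <- c(plasma_membrane = 0.21, intracytoplasmic_cisternae = 0.67,
            flagellum = 0.12)
  for (cmp in names(want)) {
    se <- sqrt(want[[cmp]] * (1 - want[[cmp]]) / n)
    expect_lt(abs(pooled[[cmp]] / n - want[[cmp]]), 4 * se)
  }
})
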