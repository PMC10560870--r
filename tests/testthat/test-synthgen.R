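test_that("design realization respects the schedule, dropout and seed", {
  # no dropout: one row per hive x timepoint
  sp <- designSpec(nBeekeepers = 1, hivesPerBeekeeper = 2, nSites = 2,
                   missingnessRate = 0)
  d <- generateDesign(sp, seed = 3)
  expect_equal(nrow(d), 6L)
  expect_equal(sort(unique(as.character(d$timepoint))),
               sort(c("June", "July", "August")))

  # determinism: same seed, identical frames
  expect_identical(generateDesign(sp, seed = 11),
                   generateDesign(sp, seed = 11))
  expect_false(identical(generateDesign(sp, seed = 11)$totalReads,
                         generateDesign(sp, seed = 12)$totalReads))

  # default scale mimics the study: ~115 realized samples out of 123
  d0 <- generateDesign(designSpec(), seed = 1)
  expect_true(nrow(d0) >= 100 && nrow(d0) <= 123)
  expect_equal(length(unique(d0$hive)), 41L)
  expect_equal(length(unique(d0$beekeeper)), 14L)
  expect_equal(length(unique(d0$site)), 30L)

  # hive -> beekeeper -> site assignments fixed across time points
  map <- unique(d0[, c("hive", "beekeeper", "site")])
  expect_equal(nrow(map), 41L)

  # invalid designs rejected
  expect_error(designSpec(nBeekeepers = 2, hivesPerBeekeeper = 1,
                          nSites = 5), "exceeds")
  expect_error(designSpec(missingnessRate = 1), "missingnessRate")
})

test_that("truth draws share seasonal tendencies within trait groups", {
  sp <- smallDesignSpec()
  tr <- guildTraits(8)

  # degenerate noise: genera of one group share identical coefficients
  t0 <- drawTruth(sp, tr, zeroScaleHyper(sigma2Beta = 1e-12), seed = 4)
  early <- tr$genus[tr$functionalGroup == "early"]
  expect_lt(max(apply(t0$betaOcc[, early, drop = FALSE], 1, sd)), 1e-5)

  # group means recover the trait regression: 10,000 genera, 3 SE
  big <- guildTraits(10000)
  tb <- drawTruth(sp, big, zeroScaleHyper(sigma2Beta = 0.25), seed = 5)
  for (g in c("early", "late")) {
    idx <- big$functionalGroup == g
    se <- sqrt(0.25 / sum(idx))
    est <- rowMeans(tb$betaOcc[, idx, drop = FALSE])
    expect_true(all(abs(est - .seasonalGamma()$occ[g, ]) < 3 * se))
  }

  expect_error(drawTruth(sp, guildTraits(0), zeroScaleHyper(), seed = 1),
               "empty")
})

test_that("counts obey the depth constraint and the probit margin", {
  sp <- smallDesignSpec()
  tr <- oneGroupTraits(30)
  # saturated occurrence: intercept +10, no random effects
  occ <- rbind(only = c(10, 0, 0, 0))
  ab <- rbind(only = c(-3, 0, 0, 0))
  colnames(occ) <- colnames(ab) <-
    c("(Intercept)", "timeT2", "timeT3", "logReads")
  hy <- truthHyper(gamma = list(occ = occ, abund = ab), sigma2Beta = 0,
                   levelScales = c(sample = 0, site = 0, hive = 0,
                                   beekeeper = 0),
                   dominance = NULL, blankRate = 0, nBlankGenera = 0)
  d <- generateDesign(sp, seed = 6)
  x <- generateCounts(d, drawTruth(sp, tr, hy, seed = 6), seed = 6)
  expect_equal(unname(colSums(countsMatrix(x))), d$totalReads)
  # every genus present everywhere (depth 1e5 over 30 genera cannot
  # starve a weight of its reads at these abundances)
  expect_true(all(countsMatrix(x) > 0))

  # intercept-only occurrence at zero: prevalence ~ Phi(0) = 0.5
  hy0 <- nullHyper()
  x0 <- generateCounts(d, drawTruth(sp, oneGroupTraits(60), hy0,
                                    seed = 7), seed = 7)
  truthY <- truthParams(x0)
  prev <- mean(countsMatrix(x0) > 0)
  n <- length(countsMatrix(x0))
  # multinomial zeros can only push prevalence below the Bernoulli margin
  expect_lt(abs(prev - 0.5), 3 * sqrt(0.25 / n) + 0.02)

  expect_error(generateCounts(transform(d, totalReads = 0),
                              drawTruth(sp, tr, hy, seed = 1), seed = 1),
               "depth")
})

test_that("RRA closure and full determinism hold for generated data", {
  x <- simulateHoneyData(nGenera = 25, spec = smallDesignSpec(), seed = 9)
  rra <- rraMatrix(computeRRA(x))
  expect_equal(unname(colSums(rra)), rep(1, ncol(rra)), tolerance = 1e-9)

  y <- simulateHoneyData(nGenera = 25, spec = smallDesignSpec(), seed = 9)
  expect_identical(countsMatrix(x), countsMatrix(y))
  expect_identical(blankCounts(x), blankCounts(y))
})

test_that("site factors decay with distance and decouple at tiny range", {
  coords <- cbind(c(0, 0.5, 8), c(0, 0, 8))
  sp <- designSpec(nBeekeepers = 3, hivesPerBeekeeper = 1, nSites = 3,
                   siteCoords = coords, missingnessRate = 0)
  d <- generateDesign(sp, seed = 1)
  draw <- function(range, seed) {
    occ <- rbind(only = c(0, 0, 0, 0))
    ab <- rbind(only = c(-3.5, 0, 0, 0))
    colnames(occ) <- colnames(ab) <-
      c("(Intercept)", "timeT2", "timeT3", "logReads")
    tr <- drawTruth(sp, oneGroupTraits(5),
                    truthHyper(gamma = list(occ = occ, abund = ab),
                               levelScales = c(sample = 0, site = 1,
                                               hive = 0, beekeeper = 0),
                               nFactors = 1, spatialRange = range,
                               dominance = NULL, blankRate = 0,
                               nBlankGenera = 0),
                    seed = seed)
    set.seed(seed)
    f <- honeyJSDM:::.drawLevelFactors(d, tr, 1)$site$eta
    # eta rows follow site levels S01..S03 = coords rows 1..3
    as.numeric(f)
  }
  reps <- t(vapply(1:400, function(s) draw(range = 3, seed = s),
                   numeric(3)))
  cNear <- cor(reps[, 1], reps[, 2])   # distance 0.5
  cFar <- cor(reps[, 1], reps[, 3])    # distance ~11.3
  expect_gt(cNear, 0.7)
  expect_lt(abs(cFar), 0.2)
  expect_gt(cNear, cFar + 0.4)

  reps0 <- t(vapply(1:400, function(s) draw(range = 1e-6, seed = s),
                    numeric(3)))
  expect_lt(abs(cor(reps0[, 1], reps0[, 2])), 3 / sqrt(400))
})
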