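test_that("Tjur's R2 matches hand-computed fixtures and stays in range", {
  expect_equal(tjurR2(c(1, 0), c(0.8, 0.3)), 0.5)
  expect_equal(tjurR2(c(1, 1, 0, 0), c(1, 1, 0, 0)), 1)   # perfect
  expect_equal(tjurR2(c(1, 0, 1), c(0.4, 0.4, 0.4)), 0)   # constant
  expect_true(is.na(tjurR2(c(1, 1), c(0.2, 0.9))))        # one class
  set.seed(1)
  for (i in 1:20) {
    y <- rbinom(30, 1, 0.5); p <- runif(30)
    if (all(y == y[1])) next
    expect_true(abs(tjurR2(y, p)) <= 1)
  }
})

test_that("AUC uses the mid-rank tie convention and matches brute force", {
  expect_equal(aucScore(c(1, 1, 0), c(0.9, 0.4, 0.5)), 0.5)
  expect_equal(aucScore(c(1, 0), c(0.9, 0.1)), 1)
  expect_equal(aucScore(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_true(is.na(aucScore(c(0, 0), c(0.2, 0.9))))
  set.seed(2)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    y <- rbinom(n, 1, 0.5)
    p <- round(runif(n), 2)                 # rounded -> real ties occur
    if (all(y == y[1])) next
    expect_identical(aucScore(y, p), aucBrute(y, p))
    # inverted scores flip the AUC (tie-free check)
    p2 <- runif(n)
    expect_equal(aucScore(y, p2) + aucScore(y, -p2), 1)
  }
})

test_that("linear R2 is affine-invariant and vanishes for pure noise", {
  z <- rnorm(50)
  expect_equal(r2Linear(z, z), 1)
  expect_equal(r2Linear(z, 2 + 3 * z), 1)
  expect_true(is.na(r2Linear(z, rep(1, 50))))
  set.seed(3)
  zo <- rnorm(4000); zp <- rnorm(4000)
  expect_lt(r2Linear(zo, zp), (3 / sqrt(4000))^2 * 3)
  # NA cells (absences) are excluded
  zo[1:10] <- NA
  expect_equal(r2Linear(zo, zo + 0), 1)
})

test_that("Omega equals the formula, the oracle, and makes sound calls", {
  # single draw: beta_T2 = [1,1], beta_T3 = [0,0] -> off-diagonal 1
  om1 <- omegaMatrix(list(betaT2 = matrix(c(1, 1), 2, 1),
                          betaT3 = matrix(c(0, 0), 2, 1)),
                     threshold = 0.9)
  expect_equal(om1@omegaMean[1, 2], 1)

  # a genus with zero seasonal response: zero row, no sign calls
  bT2 <- rbind(A = rnorm(200, 2, 0.1), B = rep(0, 200))
  bT3 <- rbind(A = rnorm(200, 1, 0.1), B = rep(0, 200))
  om0 <- omegaMatrix(list(betaT2 = bT2, betaT3 = bT3))
  expect_equal(unname(om0@omegaMean["B", ]), c(0, 0))
  expect_equal(unname(om0@signCall["B", ]), c(0L, 0L))

  # diagonal nonnegative in every draw (sum of squares) and symmetry
  set.seed(4)
  b2 <- matrix(rnorm(10 * 200), 10, 200,
               dimnames = list(paste0("G", 1:10), NULL))
  b3 <- matrix(rnorm(10 * 200), 10, 200, dimnames = dimnames(b2))
  om <- omegaMatrix(list(betaT2 = b2, betaT3 = b3))
  expect_true(all(diag(om@omegaMean) >= 0))
  expect_equal(om@omegaMean, t(om@omegaMean))

  # vectorized path equals brute-force pair/draw enumeration
  br <- omegaBrute(b2, b3)
  expect_equal(unname(om@omegaMean), br$mean, tolerance = 1e-12)
  expect_equal(unname(om@pPos), br$pos, tolerance = 1e-12)
  expect_equal(unname(om@pNeg), br$neg, tolerance = 1e-12)

  # concentrated positive responses give a confident positive call
  bP <- matrix(rnorm(2 * 1000, 2, 0.1), 2, 1000,
               dimnames = list(c("x", "y"), NULL))
  omP <- omegaMatrix(list(betaT2 = bP, betaT3 = bP * 0))
  expect_gt(omP@pPos["x", "y"], 0.999)
  expect_equal(omP@signCall["x", "y"], 1L)

  expect_error(omegaMatrix(list(betaT2 = matrix(1, 1, 5),
                                betaT3 = matrix(1, 1, 5))), "2 genera")
})

# minimal probit fit with prescribed beta draws (fixed-effect machinery only)
fakeProbitFit <- function(bDraws, n = 30) {
  D <- dim(bDraws)[3]; J <- dim(bDraws)[2]
  sf <- data.frame(sample = paste0("s", 1:n),
                   hive = "H1", beekeeper = "B1", site = "S1",
                   siteX = 0, siteY = 0,
                   timepoint = factor(rep(c("June", "July", "August"),
                                          length.out = n),
                                      levels = c("June", "July",
                                                 "August")),
                   totalReads = round(seq(8e4, 1.2e5, length.out = n)))
  spec <- makeModelSpec(sf, NULL, genusNames = paste0("G", seq_len(J)),
                        randomLevels = character(0))
  new("HurdleFit", family = "probit", beta = bDraws,
      gamma = array(0, c(1, 4, D)), V = array(0, c(4, 4, D)),
      sigma2 = matrix(0, 0, 0), lambda = list(), eta = list(),
      alpha = list(), chain = rep(1L, D), spec = spec,
      schedule = McmcSchedule(1, D, 0, 1))
}

test_that("seasonal predictions classify trends at the 95% rule", {
  D <- 400
  mk <- function(bT3draws) {
    b <- array(0, c(4, 3, D),
               dimnames = list(c("(Intercept)", "timeT2", "timeT3",
                                 "logReads"),
                               paste0("G", 1:3), NULL))
    b["timeT3", 1, ] <- bT3draws          # G1: prescribed August effect
    b["timeT3", 2, ] <- 5                 # G2: certain increase
    b["timeT3", 3, ] <- 0                 # G3: exactly no effect
    b
  }
  set.seed(5)
  fit <- fakeProbitFit(mk(rnorm(D, 0, 0.5)))
  sp <- predictSeasonal(fit)
  # scattered-around-zero effect: pIncrease near 1/2, no call
  expect_lt(abs(sp@pIncrease[1] - 0.5), 3 * sqrt(0.25 / D) + 0.05)
  expect_equal(unname(sp@trendCall[1]), "none")
  expect_equal(unname(sp@pIncrease[2]), 1)
  expect_equal(unname(sp@trendCall[2]), "increase")
  # degenerate zero effect ties out to one half
  expect_equal(unname(sp@pIncrease[3]), 0.5)
  expect_equal(unname(sp@trendCall[3]), "none")
  # probit identity: zero linear predictor -> probability one half
  expect_equal(unname(sp@probMean[3, "T1"]), 0.5)
  expect_equal(unname(sp@probMean[3, "T3"]), 0.5)
})

test_that("variance partition normalizes, and a lone source takes all", {
  D <- 5; J <- 4; U <- 6
  b <- array(0, c(4, J, D),
             dimnames = list(c("(Intercept)", "timeT2", "timeT3",
                               "logReads"), paste0("G", 1:J), NULL))
  fit <- fakeProbitFit(b, n = 12)
  # attach a single random level with nonzero loadings
  lv <- list(sample = list(name = "sample",
                           units = factor(paste0("u", 1:U)),
                           nFactors = 2L, spatial = FALSE, coords = NULL))
  fit@spec@randomLevels <- lv
  fit@lambda <- list(sample = array(rnorm(2 * J * D), c(2, J, D)))
  fit@eta <- list(sample = array(rnorm(U * 2 * D), c(U, 2, D)))
  vp <- variancePartition(fit)
  expect_equal(unname(rowSums(vp@fractions)), rep(1, J), tolerance = 1e-9)
  # no fixed-effect variance: the lone random level owns everything
  expect_equal(unname(vp@fractions[, "sample"]), rep(1, J))

  # compensating rescale of loadings and factors leaves fractions intact
  fit2 <- fit
  fit2@beta["timeT3", , ] <- rnorm(J * D)   # give time some variance
  vp1 <- variancePartition(fit2)
  fit3 <- fit2
  fit3@lambda$sample <- fit3@lambda$sample * 5
  fit3@eta$sample <- fit3@eta$sample / 5
  vp2 <- variancePartition(fit3)
  expect_equal(vp1@fractions, vp2@fractions, tolerance = 1e-9)

  # group averages are means of genus fractions, in percent
  tr <- data.frame(genus = paste0("G", 1:J),
                   taxonomicGroup = c("a", "a", "b", "b"),
                   functionalGroup = "f")
  vg <- variancePartition(fit2, tr)
  expect_equal(vg@groupMeans$taxonomicGroup["a", ],
               100 * colMeans(vg@fractions[1:2, ]))
})

test_that("cross-validation partitions deterministically", {
  x <- simulateHoneyData(nGenera = 10, spec = smallDesignSpec(), seed = 51)
  resp <- rawResponse(x)
  sch <- McmcSchedule(1, 60, 20, 2)
  cv1 <- crossValidate(resp, schedule = sch, seed = 3,
                       fitAbundanceArm = FALSE,
                       randomLevels = character(0))
  cv2 <- crossValidate(resp, schedule = sch, seed = 3,
                       fitAbundanceArm = FALSE,
                       randomLevels = character(0))
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$P, cv2$P)
  expect_equal(sort(unique(cv1$folds)), 1:2)
  expect_false(anyNA(cv1$P))
})

test_that("hurdle expectation combines occurrence and abundance arms", {
  x <- simulateHoneyData(nGenera = 10, spec = smallDesignSpec(), seed = 61)
  resp <- rawResponse(x)
  sch <- McmcSchedule(1, 80, 30, 2)
  fo <- fitOccurrence(resp, schedule = sch, seed = 1,
                      randomLevels = character(0))
  fa <- fitAbundance(resp, schedule = sch, seed = 2,
                     randomLevels = character(0))
  ex <- expectedAbundance(fo, fa)
  expect_true(all(ex > 0))
  expect_true(all(ex <= predictResponses(fo) *
                    exp(predictResponses(fa) +
                          max(rowMeans(fa@sigma2)) / 2) + 1e-12))
})
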