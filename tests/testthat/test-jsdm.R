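# Sampler-level checks. The heavier parameter-recovery runs live in
# test-acceptance.R; these cover the accounting, the conjugate sub-case
# against a numerical-integration oracle, reproducibility, and the
# reduction to genus-wise maximum likelihood when random scales vanish.

test_that("retained-draw accounting matches the schedule arithmetic", {
  long <- McmcSchedule(4, 375000, 125000, 1000)
  expect_equal(retainedDraws(long), list(perChain = 250L, total = 1000L))
  expect_equal(retainedDraws(McmcSchedule(1, 100, 0, 1)),
               list(perChain = 100L, total = 100L))
  expect_equal(retainedDraws(McmcSchedule(2, 1000, 500, 10)),
               list(perChain = 50L, total = 100L))
  expect_error(McmcSchedule(2, 100, 100, 1), "burn-in")
})

test_that("thin=1, burnin=0 stores every sweep of every chain", {
  set.seed(1)
  Y <- matrix(rbinom(40, 1, 0.5), 4, 10,
              dimnames = list(paste0("G", 1:4), paste0("s", 1:10)))
  spec <- new("HurdleModelSpec",
              X = matrix(1, 10, 1, dimnames = list(NULL, "(Intercept)")),
              fixedBlocks = list(), traitDesign = matrix(1, 4, 1),
              randomLevels = list(), priors = defaultPriors(),
              genusNames = paste0("G", 1:4))
  fit <- fitOccurrence(Y, spec = spec,
                       schedule = McmcSchedule(3, 20, 0, 1), seed = 5)
  expect_equal(dim(fit@beta)[3], 60L)
  expect_equal(as.integer(table(fit@chain)), rep(20L, 3))
})

test_that("intercept-only probit posterior matches grid integration", {
  set.seed(42)
  n <- 120
  y <- rbinom(n, 1, 0.5)
  Y <- matrix(y, ncol = n, dimnames = list("G1", paste0("s", 1:n)))
  fit <- fitOccurrence(Y, spec = interceptOnlySpec(n),
                       schedule = McmcSchedule(4, 3000, 500, 2), seed = 3)
  est <- pnorm(fit@beta[1, 1, ])
  # Monte-Carlo SE from the spread of per-chain means
  chainMeans <- tapply(est, fit@chain, mean)
  se <- sd(chainMeans) / sqrt(length(chainMeans))
  expect_lt(abs(mean(est) - probitOracle(y)), 3 * se + 0.002)
})

test_that("identical seed and schedule reproduce draws exactly", {
  x <- simulateHoneyData(nGenera = 10, spec = smallDesignSpec(), seed = 31)
  resp <- rawResponse(x)
  sch <- McmcSchedule(2, 60, 20, 2)
  f1 <- fitOccurrence(resp, schedule = sch, seed = 7, nFactors = 2)
  f2 <- fitOccurrence(resp, schedule = sch, seed = 7, nFactors = 2)
  expect_identical(f1@beta, f2@beta)
  expect_identical(f1@lambda, f2@lambda)
  f3 <- fitOccurrence(resp, schedule = sch, seed = 8, nFactors = 2)
  expect_false(identical(f1@beta, f3@beta))
})

test_that("with zero random scales the model reduces to genus-wise fits", {
  # large-n intercept-only comparison against glm maximum likelihood
  set.seed(9)
  n <- 600
  p0 <- c(0.25, 0.5, 0.8)
  Y <- t(vapply(p0, function(p) rbinom(n, 1, p), numeric(n)))
  dimnames(Y) <- list(paste0("G", 1:3), paste0("s", 1:n))
  spec <- new("HurdleModelSpec",
              X = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
              fixedBlocks = list(), traitDesign = diag(3),
              randomLevels = list(),
              priors = defaultPriors(gammaVar = 100),
              genusNames = paste0("G", 1:3))
  fit <- fitOccurrence(Y, spec = spec,
                       schedule = McmcSchedule(2, 1500, 500, 2), seed = 2)
  post <- rowMeans(fit@beta[1, , ])
  mle <- vapply(1:3, function(j)
    unname(coef(glm(Y[j, ] ~ 1, family = binomial("probit")))),
    numeric(1))
  expect_equal(unname(post), mle, tolerance = 0.06)
})

test_that("the gaussian arm concentrates on a noiseless linear signal", {
  # Z exactly equals the fixed-effect predictor: the posterior pulls the
  # residual variance well below its prior mean and recovers beta
  x <- simulateHoneyData(nGenera = 8, spec = smallDesignSpec(), seed = 41)
  sf <- sampleFrame(x)
  spec <- makeModelSpec(sf, NULL, genusNames = paste0("G", 1:8),
                        randomLevels = character(0))
  set.seed(41)
  B <- matrix(rnorm(4 * 8, sd = 0.5), 4, 8)
  B[1, ] <- B[1, ] - 3
  Z <- t(spec@X %*% B)
  dimnames(Z) <- list(paste0("G", 1:8), sf$sample)
  fit <- fitAbundance(Z, spec = spec,
                      schedule = McmcSchedule(2, 1200, 400, 2), seed = 6)
  expect_gt(cor(as.numeric(B), as.numeric(betaMeans(fit))), 0.999)
  priorMean <- defaultPriors()$bSigma / (defaultPriors()$aSigma - 1)
  expect_lt(max(rowMeans(fit@sigma2)), priorMean / 5)

  # an all-missing (or nearly) genus is rejected up front
  Zbad <- Z; Zbad[3, -1] <- NA
  expect_error(fitAbundance(Zbad, spec = spec), "fewer than 2")
})

test_that("PSRF flags divergence and passes identical-distribution chains", {
  set.seed(13)
  same <- cbind(rnorm(10000), rnorm(10000))
  expect_lt(psrf(same), 1.05)

  far <- cbind(rnorm(1000, 0, 0.01), rnorm(1000, 100, 0.01))
  expect_gt(psrf(far), 100)

  # duplicated chains: B = 0, PSRF = sqrt((n-1)/n)
  ch <- rnorm(500)
  expect_equal(psrf(cbind(ch, ch)), sqrt(499 / 500), tolerance = 1e-12)

  expect_error(psrf(matrix(rnorm(10), ncol = 1)), "2 chains")
})
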