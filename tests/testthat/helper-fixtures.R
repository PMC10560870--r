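# Shared fixtures built in code. Heavier objects (MCMC fits) are memoized
# so several test files can reuse one fit.

.fixtureCache <- new.env(parent = emptyenv())

memoFixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, builder(), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

# a small design: 6 beekeepers x 3 hives x 3 timepoints, no dropout
smallDesignSpec <- function(nSites = 12, missing = 0, depthMedian = 1e5)
  designSpec(nBeekeepers = 6, hivesPerBeekeeper = 3, nSites = nSites,
             missingnessRate = missing, depthMedian = depthMedian,
             depthSdlog = 0.4)

# recovery-scale design: ~150 samples
recoveryDesignSpec <- function()
  designSpec(nBeekeepers = 18, hivesPerBeekeeper = 3, nSites = 20,
             missingnessRate = 0.08, depthMedian = 1e5, depthSdlog = 0.4)

# hyperparameters with all random-effect scales zero (independent
# genus-wise regressions), no dominance spikes, clean blank
zeroScaleHyper <- function(sigma2Beta = 0.25, gamma = .seasonalGamma()) {
  truthHyper(gamma = gamma, sigma2Beta = sigma2Beta,
             levelScales = c(sample = 0, site = 0, hive = 0,
                             beekeeper = 0),
             dominance = NULL, blankRate = 0, nBlankGenera = 0)
}

# two opposite seasonal guilds: "early" genera peak in June, "late" ones
# in August, with seasonal abundance effects kept at zero so the
# compositional normalizer stays stable
.seasonalGamma <- function(a = 1.2) {
  occ <- rbind(early = c(0.3, -a, -2 * a, 0.3),
               late = c(-0.3, a, 2 * a, 0.3))
  abund <- rbind(early = c(-3.5, 0, 0, 0),
                 late = c(-3.5, 0, 0, 0))
  colnames(occ) <- colnames(abund) <-
    c("(Intercept)", "timeT2", "timeT3", "logReads")
  list(occ = occ, abund = abund)
}

guildTraits <- function(nGenera = 20) {
  data.frame(genus = sprintf("G%03d", seq_len(nGenera)),
             taxonomicGroup = rep(c("plant", "bacteria"),
                                  length.out = nGenera),
             functionalGroup = rep(c("early", "late"),
                                   each = ceiling(nGenera / 2))[
                                     seq_len(nGenera)],
             stringsAsFactors = FALSE)
}

# aseasonal hyper: no fixed-effect signal at all (null simulations)
nullHyper <- function() {
  occ <- rbind(only = c(0, 0, 0, 0))
  abund <- rbind(only = c(-3.5, 0, 0, 0))
  colnames(occ) <- colnames(abund) <-
    c("(Intercept)", "timeT2", "timeT3", "logReads")
  truthHyper(gamma = list(occ = occ, abund = abund), sigma2Beta = 0,
             levelScales = c(sample = 0, site = 0, hive = 0,
                             beekeeper = 0),
             dominance = NULL, blankRate = 0, nBlankGenera = 0)
}

oneGroupTraits <- function(nGenera, group = "only") {
  data.frame(genus = sprintf("G%03d", seq_len(nGenera)),
             taxonomicGroup = "x", functionalGroup = group,
             stringsAsFactors = FALSE)
}

# hurdle response straight from generated counts, without thresholds,
# keeping the genus <-> truth alignment simple
rawResponse <- function(x, minPrevalence = 0.05) {
  resp <- buildHurdleResponse(computeRRA(x))
  prevalenceFilter(resp, minPrevalence)
}

# brute-force AUC over all presence-absence pairs (oracle)
aucBrute <- function(y, p) {
  i1 <- which(y == 1); i0 <- which(y == 0)
  if (!length(i1) || !length(i0)) return(NA_real_)
  s <- 0
  for (a in i1) for (b in i0)
    s <- s + (p[a] > p[b]) + 0.5 * (p[a] == p[b])
  s / (length(i1) * length(i0))
}

# brute-force Omega summary by looping pairs and draws (oracle)
omegaBrute <- function(bT2, bT3, threshold = 0.9) {
  J <- nrow(bT2); D <- ncol(bT2)
  mean <- matrix(0, J, J); pos <- matrix(0, J, J); neg <- matrix(0, J, J)
  for (j1 in seq_len(J)) for (j2 in seq_len(J)) {
    om <- numeric(D)
    for (d in seq_len(D))
      om[d] <- bT2[j1, d] * bT2[j2, d] + bT3[j1, d] * bT3[j2, d]
    mean[j1, j2] <- base::mean(om)
    pos[j1, j2] <- base::mean(om > 0)
    neg[j1, j2] <- base::mean(om < 0)
  }
  list(mean = mean, pos = pos, neg = neg)
}

# grid-integration oracle for the intercept-only probit posterior with a
# N(0, 1) prior: returns the exact posterior mean of pnorm(beta0)
probitOracle <- function(y, priorSd = 1) {
  k <- sum(y); n <- length(y)
  grid <- seq(-6, 6, length.out = 4001)
  logp <- dnorm(grid, 0, priorSd, log = TRUE) +
    k * pnorm(grid, log.p = TRUE) +
    (n - k) * pnorm(-grid, log.p = TRUE)
  w <- exp(logp - max(logp)); w <- w / sum(w)
  sum(w * pnorm(grid))
}

# intercept-only probit model spec (single genus), with the trait
# regression pinned near zero and the coefficient covariance pinned near
# one so the effective prior on beta0 is N(0, 1)
interceptOnlySpec <- function(n, genus = "G1") {
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  new("HurdleModelSpec", X = X, fixedBlocks = list(),
      traitDesign = matrix(1, 1, 1, dimnames = list(genus, "(Intercept)")),
      randomLevels = list(),
      priors = defaultPriors(gammaVar = 1e-8, f0 = 1e6, V0scale = 1e6),
      genusNames = genus)
}
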