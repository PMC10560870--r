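## Synthetic honey-metagenome generator.
##
## Emulates the generative structure the hurdle joint model assumes: a
## hierarchical apiary design (beekeepers > hives at sites, sampled at three
## time points), probit occurrence and log-normal relative-weight abundance
## with trait-linked seasonal coefficients and crossed latent-factor random
## effects, multinomial read allocation at a log-normally drawn sequencing
## depth, occasional single-taxon dominance spikes and low-level blank
## contamination.

#' Describe a hierarchical apiary sampling design
#'
#' Defaults mirror the scale of a season-long apiary survey: 14 beekeepers
#' managing 41 hives placed on 30 sites, honey sampled at three time points
#' (June, July, August), with a 7% chance that a scheduled hive x time
#' sample is lost, and per-sample genus-assigned read totals drawn from a
#' log-normal law with median 2e7.
#'
#' @param nBeekeepers number of beekeepers.
#' @param hivesPerBeekeeper integer scalar or vector of hive counts per
#'   beekeeper (default: 13 beekeepers with 3 hives and one with 2, i.e. 41).
#' @param nSites number of apiary sites; must not exceed the hive total.
#' @param siteCoords optional nSites x 2 matrix of planar coordinates
#'   (arbitrary units); drawn uniformly on a 10 x 10 square when `NULL`.
#' @param timepoints ordered time-point labels, at least two.
#' @param missingnessRate probability in [0, 1) that a scheduled sample is
#'   absent.
#' @param depthMedian,depthSdlog median and log-sd of the per-sample total
#'   read count (log-normal).
#' @return A list of class `"designSpec"`.
#' @export
designSpec <- function(nBeekeepers = 14,
                       hivesPerBeekeeper = c(rep(3L, 13), 2L),
                       nSites = 30,
                       siteCoords = NULL,
                       timepoints = c("June", "July", "August"),
                       missingnessRate = 0.07,
                       depthMedian = 2e7,
                       depthSdlog = 0.5) {
  if (length(hivesPerBeekeeper) == 1L)
    hivesPerBeekeeper <- rep(as.integer(hivesPerBeekeeper), nBeekeepers)
  if (length(hivesPerBeekeeper) != nBeekeepers)
    stop("hivesPerBeekeeper must have one entry per beekeeper")
  nHives <- sum(hivesPerBeekeeper)
  if (nSites > nHives)
    stop("nSites exceeds the number of hives; no assignment rule exists")
  if (missingnessRate < 0 || missingnessRate >= 1)
    stop("missingnessRate must lie in [0, 1)")
  if (length(timepoints) < 2L)
    stop("need at least two time points")
  if (depthMedian <= 0) stop("depth must be positive")
  structure(list(nBeekeepers = nBeekeepers,
                 hivesPerBeekeeper = as.integer(hivesPerBeekeeper),
                 nSites = as.integer(nSites), siteCoords = siteCoords,
                 timepoints = timepoints,
                 missingnessRate = missingnessRate,
                 depthMedian = depthMedian, depthSdlog = depthSdlog),
            class = "designSpec")
}

#' Realize the per-sample design table
#'
#' Assigns hives to beekeepers (consecutive blocks) and to sites (every site
#' receives at least one hive, surplus hives placed at random), schedules one
#' sample per hive and time point, drops scheduled samples independently with
#' the design's missingness rate, and draws a sequencing depth per realized
#' sample. Assignments are fixed across time points and the result is
#' deterministic for a fixed seed.
#'
#' @param spec a [designSpec()].
#' @param seed integer seed.
#' @return data.frame with columns `sample`, `hive`, `beekeeper`, `site`,
#'   `siteX`, `siteY`, `timepoint`, `totalReads`.
#' @export
generateDesign <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "designSpec"))
  set.seed(seed)
  nHives <- sum(spec$hivesPerBeekeeper)
  hive <- sprintf("H%02d", seq_len(nHives))
  beekeeper <- sprintf("B%02d",
                       rep(seq_len(spec$nBeekeepers),
                           spec$hivesPerBeekeeper))
  coords <- spec$siteCoords
  if (is.null(coords))
    coords <- cbind(runif(spec$nSites, 0, 10), runif(spec$nSites, 0, 10))
  # every site hosts >= 1 hive, remaining hives placed uniformly
  siteIdx <- c(sample(spec$nSites),
               sample(spec$nSites, nHives - spec$nSites, replace = TRUE))
  site <- sprintf("S%02d", siteIdx)
  grid <- expand.grid(hiveIdx = seq_len(nHives),
                      timepoint = spec$timepoints,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keep <- runif(nrow(grid)) >= spec$missingnessRate
  grid <- grid[keep, , drop = FALSE]
  depth <- round(rlnorm(nrow(grid), meanlog = log(spec$depthMedian),
                        sdlog = spec$depthSdlog))
  out <- data.frame(
    sample = sprintf("%s_%s", hive[grid$hiveIdx], grid$timepoint),
    hive = hive[grid$hiveIdx],
    beekeeper = beekeeper[grid$hiveIdx],
    site = site[grid$hiveIdx],
    siteX = coords[siteIdx[grid$hiveIdx], 1],
    siteY = coords[siteIdx[grid$hiveIdx], 2],
    timepoint = factor(grid$timepoint, levels = spec$timepoints),
    totalReads = pmax(depth, 1),
    stringsAsFactors = FALSE)
  rownames(out) <- out$sample
  out[order(out$hive, out$timepoint), ]
}

#' Simulate a genus trait table
#'
#' Draws genera from four broad taxonomic groups at proportions matching a
#' typical honey genome-skimming profile (plants : bacteria : fungi : viruses
#' roughly 49 : 45 : 23 : 3) and nests a functional group within each:
#' plants are nectar- or non-nectar-producing; bacteria are bee gut, beehive
#' or neutral; fungi are plant or bee pathogens; viruses are bee pathogens.
#'
#' @param nGenera number of genera.
#' @param seed integer seed.
#' @return data.frame with columns `genus`, `taxonomicGroup`,
#'   `functionalGroup`.
#' @export
simulateTraits <- function(nGenera = 40, seed = 1) {
  set.seed(seed)
  taxProb <- c(plant = 49, bacteria = 45, fungi = 23, virus = 3) / 120
  tax <- sample(names(taxProb), nGenera, replace = TRUE, prob = taxProb)
  fun <- vapply(tax, function(t) switch(t,
    plant = sample(c("nectar_plant", "no_nectar_plant"), 1,
                   prob = c(0.6, 0.4)),
    bacteria = sample(c("bee_gut", "beehive", "neutral"), 1,
                      prob = c(0.4, 0.3, 0.3)),
    fungi = sample(c("plant_pathogen", "bee_pathogen"), 1,
                   prob = c(0.6, 0.4)),
    virus = "bee_pathogen"), character(1))
  data.frame(genus = sprintf("G%03d", seq_len(nGenera)),
             taxonomicGroup = tax, functionalGroup = fun,
             stringsAsFactors = FALSE)
}

# Functional-group mean coefficients (intercept, July, August, log-depth)
# for the two model arms. These are the generator's study conditions:
# nectar plants and bee-associated microbes trend upward over the season,
# non-nectar plants downward, hive/neutral microbes are aseasonal.
.defaultGroupEffects <- function() {
  occ <- rbind(
    nectar_plant   = c(-0.3,  0.4,  0.9, 0.4),
    no_nectar_plant= c( 0.0, -0.5, -1.0, 0.4),
    bee_gut        = c(-0.2,  0.4,  0.9, 0.4),
    beehive        = c(-0.3,  0.0,  0.0, 0.4),
    neutral        = c(-0.5,  0.0,  0.0, 0.4),
    plant_pathogen = c(-0.5,  0.0,  0.0, 0.4),
    bee_pathogen   = c(-0.4,  0.3,  0.8, 0.4))
  abund <- rbind(
    nectar_plant   = c(-4.0,  0.2,  0.5, 0.0),
    no_nectar_plant= c(-4.0, -0.3, -0.6, 0.0),
    bee_gut        = c(-4.5,  0.2,  0.5, 0.0),
    beehive        = c(-4.5,  0.0,  0.0, 0.0),
    neutral        = c(-5.0,  0.0,  0.0, 0.0),
    plant_pathogen = c(-5.0,  0.0,  0.0, 0.0),
    bee_pathogen   = c(-4.5,  0.2,  0.4, 0.0))
  colnames(occ) <- colnames(abund) <-
    c("(Intercept)", "timeT2", "timeT3", "logReads")
  list(occ = occ, abund = abund)
}

#' Default generator hyperparameters
#'
#' @param gamma list with matrices `occ` and `abund` of functional-group
#'   mean coefficients (groups x predictors: intercept, July, August,
#'   centred log reads).
#' @param sigma2Beta variance of genus coefficients around their group mean.
#' @param levelScales named numeric, latent-factor scale per random level
#'   (standard deviation of the level's contribution to the linear
#'   predictor); zero switches a level off.
#' @param nFactors latent factors per level.
#' @param spatialRange exponential-decay range of the site factors, in
#'   coordinate units; ignored when the site scale is zero.
#' @param sigma2Resid residual variance of log abundance per genus (scalar
#'   recycled).
#' @param dominance list(nGenera, spikeFactor, spikeProb): up to `nGenera`
#'   randomly chosen taxa get their expected weight multiplied by
#'   `spikeFactor` in a `spikeProb` fraction of samples, mimicking
#'   single-taxon dominance of up to ~99% of reads.
#' @param blankRate expected blank-control reads for a handful of genera
#'   (Poisson mean); `nBlankGenera` genera are affected.
#' @param nBlankGenera number of contaminated genera in the blank.
#' @return list of class `"truthHyper"`.
#' @export
truthHyper <- function(gamma = .defaultGroupEffects(),
                       sigma2Beta = 0.25,
                       levelScales = c(sample = 0.7, site = 0.4,
                                       hive = 0.4, beekeeper = 0.4),
                       nFactors = 2,
                       spatialRange = 3,
                       sigma2Resid = 0.5,
                       dominance = list(nGenera = 3, spikeFactor = 2000,
                                        spikeProb = 0.1),
                       blankRate = 20,
                       nBlankGenera = 5) {
  stopifnot(all(sigma2Resid > 0), all(levelScales >= 0), spatialRange > 0)
  structure(list(gamma = gamma, sigma2Beta = sigma2Beta,
                 levelScales = levelScales, nFactors = nFactors,
                 spatialRange = spatialRange, sigma2Resid = sigma2Resid,
                 dominance = dominance, blankRate = blankRate,
                 nBlankGenera = nBlankGenera),
            class = "truthHyper")
}

#' Draw ground-truth generative parameters
#'
#' Genus coefficients are drawn as their functional-group mean plus
#' independent normal noise (`sigma2Beta`), so trait groups share seasonal
#' tendencies; loadings and level scales define the crossed random effects.
#'
#' @param spec a [designSpec()].
#' @param traits trait table covering all genera (see [simulateTraits()]).
#' @param hyper a [truthHyper()].
#' @param seed integer seed.
#' @return list of class `"truthParams"` with elements `betaOcc`,
#'   `betaAbund` (predictor x genus), `gamma`, `sigma2Beta`, `loadings`
#'   (per arm, per level: factor x genus), `levelScales`, `spatialRange`,
#'   `sigma2Resid`, `dominance`, `blankRate`, `traits`.
#' @export
drawTruth <- function(spec, traits, hyper = truthHyper(), seed = 1) {
  stopifnot(inherits(hyper, "truthHyper"))
  set.seed(seed)
  J <- nrow(traits)
  if (J == 0L) stop("trait table is empty")
  grp <- traits$functionalGroup
  bad <- setdiff(grp, rownames(hyper$gamma$occ))
  if (length(bad))
    stop("functional groups without effect specification: ",
         paste(unique(bad), collapse = ", "))
  if (any(table(factor(grp, levels = unique(grp))) == 0L))
    stop("empty trait groups")
  p <- ncol(hyper$gamma$occ)
  drawBeta <- function(gm) {
    mu <- t(gm[grp, , drop = FALSE])              # p x J
    mu + sqrt(hyper$sigma2Beta) * matrix(rnorm(p * J), p, J)
  }
  betaOcc <- drawBeta(hyper$gamma$occ)
  betaAbund <- drawBeta(hyper$gamma$abund)
  colnames(betaOcc) <- colnames(betaAbund) <- traits$genus
  nf <- hyper$nFactors
  levels <- names(hyper$levelScales)
  mkLoad <- function() {
    out <- lapply(levels, function(l) {
      sc <- hyper$levelScales[[l]]
      matrix(rnorm(nf * J, sd = sc / sqrt(nf)), nf, J,
             dimnames = list(NULL, traits$genus))
    })
    names(out) <- levels
    out
  }
  dom <- NULL
  if (!is.null(hyper$dominance) && hyper$dominance$nGenera > 0 && J >= 10) {
    dom <- list(genera = sample(traits$genus,
                                min(hyper$dominance$nGenera, J)),
                spikeFactor = hyper$dominance$spikeFactor,
                spikeProb = hyper$dominance$spikeProb)
  }
  blank <- setNames(numeric(J), traits$genus)
  nb <- min(hyper$nBlankGenera, J)
  if (nb > 0) blank[sample(J, nb)] <- hyper$blankRate
  structure(list(betaOcc = betaOcc, betaAbund = betaAbund,
                 gamma = hyper$gamma, sigma2Beta = hyper$sigma2Beta,
                 loadings = list(occ = mkLoad(), abund = mkLoad()),
                 levelScales = hyper$levelScales, nFactors = nf,
                 spatialRange = hyper$spatialRange,
                 sigma2Resid = rep_len(hyper$sigma2Resid, J),
                 dominance = dom, blankRate = blank, traits = traits),
            class = "truthParams")
}

# exponential spatial kernel over planar coordinates
.expKernel <- function(coords, range) {
  d <- as.matrix(dist(coords))
  if (range <= 0) return(diag(nrow(d)))
  exp(-d / range)
}

# draw per-unit latent factors for every level of one model arm
.drawLevelFactors <- function(design, truth, nf) {
  lv <- list()
  for (name in names(truth$levelScales)) {
    units <- switch(name,
                    sample = factor(design$sample, levels = design$sample),
                    factor(design[[name]]))
    U <- nlevels(units)
    if (name == "site" && truth$levelScales[[name]] > 0) {
      coords <- unique(design[, c("site", "siteX", "siteY")])
      coords <- coords[match(levels(units), coords$site), c("siteX", "siteY")]
      K <- .expKernel(as.matrix(coords), truth$spatialRange)
      L <- chol(K + 1e-8 * diag(U))
      eta <- crossprod(L, matrix(rnorm(U * nf), U, nf))
    } else {
      eta <- matrix(rnorm(U * nf), U, nf)
    }
    lv[[name]] <- list(units = units, eta = eta)
  }
  lv
}

#' Generate a synthetic honey genome-skimming dataset
#'
#' For each genus and sample, occurrence is Bernoulli with probit
#' probability from the occurrence linear predictor (fixed effects plus
#' latent-factor random effects); conditional on occurrence a log-normal
#' relative weight is drawn from the abundance predictor; weights are
#' renormalized within each sample and converted to integer counts by
#' multinomial allocation of the drawn sequencing depth. Dominance spikes
#' multiply selected genera's weights in randomly chosen samples, and a
#' blank-control vector is drawn from the per-genus contamination rates.
#' A sample in which no genus occurs has its single most probable genus
#' forced present so that the depth can be allocated.
#'
#' @param design data.frame from [generateDesign()].
#' @param truth list from [drawTruth()].
#' @param seed integer seed.
#' @return A [HoneySkimExperiment-class] with the truth attached in
#'   `metadata()`.
#' @export
generateCounts <- function(design, truth, seed = 1) {
  stopifnot(inherits(truth, "truthParams"))
  if (any(design$totalReads <= 0)) stop("depth must be positive")
  set.seed(seed)
  n <- nrow(design); J <- ncol(truth$betaOcc)
  genus <- colnames(truth$betaOcc)
  X <- cbind("(Intercept)" = 1,
             timeT2 = as.numeric(as.integer(design$timepoint) == 2L),
             timeT3 = as.numeric(as.integer(design$timepoint) == 3L),
             logReads = log(design$totalReads) -
               mean(log(design$totalReads)))
  addRanef <- function(lv, loadings) {
    R <- matrix(0, n, J)
    for (name in names(lv)) {
      f <- lv[[name]]
      R <- R + f$eta[as.integer(f$units), , drop = FALSE] %*% loadings[[name]]
    }
    R
  }
  lvOcc <- .drawLevelFactors(design, truth, truth$nFactors)
  lvAb <- .drawLevelFactors(design, truth, truth$nFactors)
  muOcc <- X %*% truth$betaOcc + addRanef(lvOcc, truth$loadings$occ)
  muAb <- X %*% truth$betaAbund + addRanef(lvAb, truth$loadings$abund)
  Y <- matrix(rbinom(n * J, 1, pnorm(muOcc)), n, J)
  logW <- muAb + matrix(rnorm(n * J, sd = rep(sqrt(truth$sigma2Resid),
                                              each = n)), n, J)
  W <- exp(logW) * Y
  if (!is.null(truth$dominance)) {
    for (g in truth$dominance$genera) {
      j <- match(g, genus)
      hit <- runif(n) < truth$dominance$spikeProb
      W[hit, j] <- exp(logW[hit, j]) * truth$dominance$spikeFactor
      Y[hit, j] <- 1
    }
  }
  empty <- rowSums(W) == 0
  if (any(empty)) {
    jmax <- max.col(muOcc[empty, , drop = FALSE])
    for (k in seq_along(which(empty))) {
      i <- which(empty)[k]
      Y[i, jmax[k]] <- 1
      W[i, jmax[k]] <- exp(logW[i, jmax[k]])
    }
  }
  counts <- matrix(0, J, n, dimnames = list(genus, design$sample))
  for (i in seq_len(n))
    counts[, i] <- rmultinom(1, size = design$totalReads[i],
                             prob = W[i, ] / sum(W[i, ]))
  blank <- rpois(J, truth$blankRate)
  names(blank) <- genus
  truth$latentOcc <- lvOcc
  truth$latentAbund <- lvAb
  HoneySkimExperiment(counts, design, traits = truth$traits,
                      blank = blank, truth = truth)
}

#' One-call synthetic dataset at a chosen scale
#'
#' Convenience wrapper chaining [generateDesign()], [simulateTraits()],
#' [drawTruth()] and [generateCounts()] with a single seed.
#'
#' @param nGenera number of genera.
#' @param spec a [designSpec()].
#' @param hyper a [truthHyper()].
#' @param seed integer seed (sub-seeds for the stages are derived from it).
#' @return A [HoneySkimExperiment-class].
#' @export
simulateHoneyData <- function(nGenera = 40, spec = designSpec(),
                              hyper = truthHyper(), seed = 1) {
  design <- generateDesign(spec, seed = seed)
  traits <- simulateTraits(nGenera, seed = seed + 1L)
  truth <- drawTruth(spec, traits, hyper, seed = seed + 2L)
  generateCounts(design, truth, seed = seed + 3L)
}
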