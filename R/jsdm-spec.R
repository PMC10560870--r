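## Model specification and MCMC accounting for the hurdle JSDM pair.

#' Default prior hyperparameters
#'
#' These are implementation defaults in the spirit of hierarchical
#' community-model software: a normal prior on the trait regression, an
#' inverse-Wishart prior on the coefficient covariance, a
#' multiplicative-gamma shrinkage prior on factor loadings, an
#' inverse-gamma prior on residual variances, and a discrete prior over a
#' grid of spatial ranges with half its mass on zero (no spatial
#' structure).
#'
#' @param gammaVar prior variance of each trait-regression coefficient.
#' @param f0,V0scale inverse-Wishart degrees of freedom offset (df = p +
#'   `f0`) and scale multiplier for the coefficient covariance.
#' @param aSigma,bSigma inverse-gamma shape and rate for residual variance.
#' @param nu,a1,a2 multiplicative-gamma shrinkage: local t-prior df `nu`,
#'   gamma shapes for the first and subsequent column multipliers.
#' @param nAlphaGrid number of nonzero grid points for the spatial range.
#' @param alphaMaxFrac largest grid value as a fraction of the maximum
#'   inter-site distance.
#' @param alphaZeroWeight prior mass on spatial range zero.
#' @return list of hyperparameters.
#' @export
defaultPriors <- function(gammaVar = 10, f0 = 1, V0scale = 1,
                          aSigma = 2, bSigma = 1,
                          nu = 3, a1 = 2, a2 = 3,
                          nAlphaGrid = 20, alphaMaxFrac = 1,
                          alphaZeroWeight = 0.5) {
  list(gammaVar = gammaVar, f0 = f0, V0scale = V0scale,
       aSigma = aSigma, bSigma = bSigma, nu = nu, a1 = a1, a2 = a2,
       nAlphaGrid = nAlphaGrid, alphaMaxFrac = alphaMaxFrac,
       alphaZeroWeight = alphaZeroWeight)
}

#' Build the model specification for one hurdle arm
#'
#' The fixed design holds an intercept, indicator columns for the second
#' and third time points (first level = June is the reference) and the
#' natural-log total reads centred at its sample mean. The trait design
#' holds an intercept plus one-hot indicators for taxonomic and functional
#' groups (reference = first level). Random levels default to sample,
#' site (spatially explicit, exponential kernel over the site
#' coordinates), hive and beekeeper, each with `nFactors` latent factors.
#'
#' @param samples per-sample design table (columns `hive`, `beekeeper`,
#'   `site`, `siteX`, `siteY`, `timepoint`, `totalReads`).
#' @param traits genus trait table (`taxonomicGroup`, `functionalGroup`),
#'   or `NULL` for an intercept-only trait design.
#' @param genusNames genera to be modelled, in response-row order.
#' @param randomLevels character subset of
#'   `c("sample", "site", "hive", "beekeeper")`; use `character(0)` for a
#'   fixed-effects-only model.
#' @param nFactors latent factors per random level (default 3).
#' @param spatialSite logical; treat the site level as spatially explicit.
#' @param priors list from [defaultPriors()].
#' @return A [HurdleModelSpec-class].
#' @export
makeModelSpec <- function(samples, traits = NULL, genusNames,
                          randomLevels = c("sample", "site", "hive",
                                           "beekeeper"),
                          nFactors = 3, spatialSite = TRUE,
                          priors = defaultPriors()) {
  tp <- factor(samples$timepoint)
  if (nlevels(tp) != 3L)
    stop("expected three time-point levels")
  X <- cbind("(Intercept)" = 1,
             timeT2 = as.numeric(as.integer(tp) == 2L),
             timeT3 = as.numeric(as.integer(tp) == 3L),
             logReads = log(samples$totalReads) -
               mean(log(samples$totalReads)))
  rownames(X) <- samples$sample
  attr(X, "logReadsCenter") <- mean(log(samples$totalReads))
  if (qr(X)$rank < ncol(X)) stop("rank-deficient fixed design")
  fixedBlocks <- list(time = c("timeT2", "timeT3"),
                      total_reads = "logReads")
  if (is.null(traits) || !nrow(traits)) {
    Tr <- matrix(1, length(genusNames), 1,
                 dimnames = list(genusNames, "(Intercept)"))
  } else {
    key <- if (!is.null(traits$genus)) traits$genus else rownames(traits)
    tr <- traits[match(genusNames, key), , drop = FALSE]
    if (anyNA(tr$taxonomicGroup))
      stop("traits do not cover all modelled genera")
    df <- data.frame(taxonomicGroup = factor(tr$taxonomicGroup),
                     functionalGroup = factor(tr$functionalGroup))
    # drop constant factors (e.g. single-group toy data)
    form <- paste(c("1", names(df)[vapply(df, nlevels, 1L) > 1L]),
                  collapse = " + ")
    Tr <- stats::model.matrix(stats::as.formula(paste("~", form)), df)
    rownames(Tr) <- genusNames
  }
  lv <- lapply(randomLevels, function(name) {
    units <- switch(name,
                    sample = factor(samples$sample,
                                    levels = samples$sample),
                    factor(samples[[name]]))
    spatial <- (name == "site") && spatialSite
    coords <- NULL
    if (spatial) {
      cc <- unique(samples[, c("site", "siteX", "siteY")])
      coords <- as.matrix(cc[match(levels(units), cc$site),
                             c("siteX", "siteY")])
    }
    list(name = name, units = units, nFactors = as.integer(nFactors),
         spatial = spatial, coords = coords)
  })
  names(lv) <- randomLevels
  new("HurdleModelSpec", X = X, fixedBlocks = fixedBlocks,
      traitDesign = Tr, randomLevels = lv, priors = priors,
      genusNames = genusNames)
}

#' Retained-draw accounting for an MCMC schedule
#'
#' @param schedule a [McmcSchedule-class].
#' @return list with `perChain = floor((nIterations - nBurnin) / thin)` and
#'   `total = perChain * nChains`. The canonical long schedule of 4 chains
#'   of 375,000 iterations with 125,000 burn-in thinned by 1,000 yields
#'   250 draws per chain and 1,000 in total.
#' @export
retainedDraws <- function(schedule) {
  stopifnot(is(schedule, "McmcSchedule"))
  validObject(schedule)
  perChain <- (schedule@nIterations - schedule@nBurnin) %/% schedule@thin
  list(perChain = perChain, total = perChain * schedule@nChains)
}
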