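## User-facing fitting functions for the hurdle model pair.

#' Fit the probit occurrence model
#'
#' Multivariate probit regression of genus presence-absence on season and
#' sequencing depth, with trait effects on the genus coefficients and
#' crossed latent-factor random effects, fitted by Gibbs sampling with
#' truncated-normal data augmentation.
#'
#' @param response a [HurdleResponse-class] (already prevalence-filtered),
#'   or a genus x sample binary matrix.
#' @param spec a [HurdleModelSpec-class]; built from `samples`/`traits`
#'   when `NULL`.
#' @param schedule a [McmcSchedule-class].
#' @param seed integer seed; chain `c` uses `seed + c - 1`.
#' @param samples,traits used to build a default spec when `spec` is
#'   `NULL` (see [makeModelSpec()]).
#' @param ... passed to [makeModelSpec()].
#' @return A [HurdleFit-class] with `family = "probit"`.
#' @export
fitOccurrence <- function(response, spec = NULL,
                          schedule = McmcSchedule(), seed = 1,
                          samples = NULL, traits = NULL, ...) {
  if (is(response, "HurdleResponse")) {
    Y <- t(response@Y)                           # samples x genera
    if (is.null(samples)) samples <- response@samples
  } else {
    Y <- t(as.matrix(response))
  }
  if (!all(Y %in% c(0, 1))) stop("Y must be binary")
  if (is.null(spec))
    spec <- makeModelSpec(samples, traits, genusNames = colnames(Y), ...)
  if (nrow(Y) != nrow(spec@X)) stop("spec not aligned to the response")
  .fitArm(Yobs = Y, Zobs = NULL, family = "probit", spec = spec,
          schedule = schedule, seed = seed)
}

#' Fit the log-abundance-given-presence model
#'
#' Gaussian regression of log RRA on the same design, evaluated on the
#' observed (presence) cells only; absent cells contribute nothing to the
#' likelihood. Per-genus residual variances are sampled.
#'
#' @inheritParams fitOccurrence
#' @param response a [HurdleResponse-class], or a genus x sample matrix of
#'   log abundances with `NA` where absent.
#' @return A [HurdleFit-class] with `family = "gaussian"`.
#' @export
fitAbundance <- function(response, spec = NULL,
                         schedule = McmcSchedule(), seed = 1,
                         samples = NULL, traits = NULL, ...) {
  if (is(response, "HurdleResponse")) {
    Z <- t(response@Z)
    if (is.null(samples)) samples <- response@samples
  } else {
    Z <- t(as.matrix(response))
  }
  nObs <- colSums(!is.na(Z))
  if (any(nObs < 2))
    stop("genus with fewer than 2 observed cells: ",
         paste(colnames(Z)[nObs < 2], collapse = ", "),
         " - exclude before fitting (see prevalenceFilter)")
  if (is.null(spec))
    spec <- makeModelSpec(samples, traits, genusNames = colnames(Z), ...)
  if (nrow(Z) != nrow(spec@X)) stop("spec not aligned to the response")
  .fitArm(Yobs = NULL, Zobs = Z, family = "gaussian", spec = spec,
          schedule = schedule, seed = seed)
}

#' Posterior mean genus coefficients
#'
#' @param fit a [HurdleFit-class].
#' @return predictor x genus matrix of posterior means.
#' @export
betaMeans <- function(fit) apply(fit@beta, c(1, 2), mean)

#' Posterior credible intervals for genus coefficients
#'
#' @param fit a [HurdleFit-class].
#' @param level credible level (default 0.95, equal-tailed).
#' @return list with predictor x genus matrices `lower` and `upper`.
#' @export
betaIntervals <- function(fit, level = 0.95) {
  a <- (1 - level) / 2
  list(lower = apply(fit@beta, c(1, 2), quantile, probs = a),
       upper = apply(fit@beta, c(1, 2), quantile, probs = 1 - a))
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance-ratio estimate per scalar
#' parameter: with `m` chains of length `n`, per-chain means and variances
#' give `W` (mean within-chain variance) and `B/n` (variance of chain
#' means), and PSRF = sqrt(((n-1)/n W + B/n) / W). Values near 1 indicate
#' convergence.
#'
#' @param x draws: a draws x chains matrix for one parameter, or a
#'   [HurdleFit-class] (PSRF computed for every genus coefficient).
#' @param ... unused.
#' @return For a matrix, a single PSRF; for a fit, a predictor x genus
#'   matrix of PSRFs.
#' @export
psrf <- function(x, ...) {
  if (is(x, "HurdleFit")) {
    ch <- x@chain
    m <- length(unique(ch))
    if (m < 2) stop("need at least 2 chains")
    d <- dim(x@beta)
    out <- matrix(NA_real_, d[1], d[2], dimnames = dimnames(x@beta)[1:2])
    for (i in seq_len(d[1]))
      for (j in seq_len(d[2]))
        out[i, j] <- psrf(matrix(x@beta[i, j, order(ch)],
                                 ncol = m))
    return(out)
  }
  x <- as.matrix(x)
  m <- ncol(x); n <- nrow(x)
  if (m < 2) stop("need at least 2 chains (or use a split-chain layout)")
  if (n < 2) stop("need at least 2 draws per chain")
  mu <- colMeans(x)
  W <- mean(apply(x, 2, var))
  B <- n * var(mu)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Credible intervals for genus-centred coefficient contrasts
#'
#' Relative read abundances are compositional: a per-sample normalizing
#' constant (the log of the summed abundance weights) is absorbed into the
#' abundance model's coefficients, shifting all genera equally. The
#' identified estimand for genus-level comparison is therefore the
#' contrast of a genus's coefficient against the across-genus mean, which
#' this computes per posterior draw.
#'
#' @param fit a [HurdleFit-class].
#' @param predictors predictor rows to summarize (default the two season
#'   indicators).
#' @param level credible level (default 0.95, equal-tailed).
#' @return list of per-predictor lists with genus-named `lower`, `upper`
#'   and `mean` of the centred contrast.
#' @export
centredBetaIntervals <- function(fit, predictors = c("timeT2", "timeT3"),
                                 level = 0.95) {
  a <- (1 - level) / 2
  out <- lapply(predictors, function(row) {
    dr <- fit@beta[row, , ]                    # genus x draw
    drC <- sweep(dr, 2, colMeans(dr))
    list(lower = apply(drC, 1, quantile, probs = a),
         upper = apply(drC, 1, quantile, probs = 1 - a),
         mean = rowMeans(drC))
  })
  names(out) <- predictors
  out
}
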