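## Post-fit summaries: predictions, fit metrics, variance partitioning,
## cross-validation, seasonal trends, and the temporal co-occurrence
## matrix Omega.

# Posterior-mean cell predictions for new or training samples.
# unitLabels: named list (per random level) of unit labels per prediction
# row; labels unseen during fitting have that level marginalized (probit:
# extra liability variance; gaussian: zero-mean contribution).
# marginalizeLevels: level names always treated as unseen.
.predictCells <- function(fit, X = fit@spec@X, unitLabels = NULL,
                          marginalizeLevels = character(0)) {
  spec <- fit@spec
  D <- dim(fit@beta)[3]; n <- nrow(X); J <- dim(fit@beta)[2]
  lvl <- spec@randomLevels
  maps <- lapply(names(lvl), function(nm) {
    if (nm %in% marginalizeLevels) return(rep(NA_integer_, n))
    lab <- if (is.null(unitLabels)) as.character(lvl[[nm]]$units)
           else as.character(unitLabels[[nm]])
    match(lab, levels(lvl[[nm]]$units))
  })
  acc <- matrix(0, n, J)
  for (d in seq_len(D)) {
    mu <- X %*% fit@beta[, , d]
    vadd <- matrix(0, n, J)
    for (li in seq_along(lvl)) {
      map <- maps[[li]]
      known <- !is.na(map)
      Lam <- fit@lambda[[li]][, , d, drop = FALSE]
      dim(Lam) <- dim(fit@lambda[[li]])[1:2]
      if (any(known)) {
        Eta <- fit@eta[[li]][, , d, drop = FALSE]
        dim(Eta) <- dim(fit@eta[[li]])[1:2]
        mu[known, ] <- mu[known, ] +
          Eta[map[known], , drop = FALSE] %*% Lam
      }
      if (any(!known))
        vadd[!known, ] <- vadd[!known, ] +
          rep(colSums(Lam^2), each = sum(!known))
    }
    acc <- acc + if (fit@family == "probit")
      pnorm(mu / sqrt(1 + vadd)) else mu
  }
  acc / D
}

#' Predicted occurrence probabilities or log abundances
#'
#' Posterior-mean predictions per sample and genus. For the probit arm the
#' occurrence probability is averaged over draws, conditioning on the
#' estimated latent factors of units seen during fitting and analytically
#' marginalizing the factors of unseen units (and of any level listed in
#' `marginalizeLevels`). For the gaussian arm the posterior-mean linear
#' predictor is returned.
#'
#' @param fit a [HurdleFit-class].
#' @param newSamples optional per-sample design table for new samples;
#'   defaults to the training design.
#' @param marginalizeLevels level names whose factors are integrated out
#'   regardless of unit identity.
#' @return genus x sample matrix of predictions.
#' @export
predictResponses <- function(fit, newSamples = NULL,
                             marginalizeLevels = character(0)) {
  spec <- fit@spec
  if (is.null(newSamples)) {
    P <- .predictCells(fit, marginalizeLevels = marginalizeLevels)
    rownames(P) <- rownames(spec@X)
  } else {
    tp <- factor(newSamples$timepoint)
    ctr <- attr(spec@X, "logReadsCenter") %||%
      mean(log(newSamples$totalReads))
    X <- cbind("(Intercept)" = 1,
               timeT2 = as.numeric(as.integer(tp) == 2L),
               timeT3 = as.numeric(as.integer(tp) == 3L),
               logReads = log(newSamples$totalReads) - ctr)
    ul <- lapply(spec@randomLevels, function(l)
      switch(l$name, sample = newSamples$sample,
             newSamples[[l$name]]))
    P <- .predictCells(fit, X = X, unitLabels = ul,
                       marginalizeLevels = marginalizeLevels)
    rownames(P) <- newSamples$sample
  }
  colnames(P) <- spec@genusNames
  t(P)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tjur's discrimination coefficient
#'
#' Mean predicted probability over presences minus mean over absences.
#' Genera with no presences or no absences are undefined (`NA`).
#'
#' @param Y binary vector or genus x sample matrix.
#' @param P predicted probabilities, same shape.
#' @return per-genus statistic in [-1, 1].
#' @export
tjurR2 <- function(Y, P) {
  f <- function(y, p) {
    if (all(y == 1) || all(y == 0)) return(NA_real_)
    mean(p[y == 1]) - mean(p[y == 0])
  }
  if (is.matrix(Y))
    vapply(seq_len(nrow(Y)), function(j) f(Y[j, ], P[j, ]), numeric(1)) |>
      setNames(rownames(Y))
  else f(Y, P)
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen presence outranks a randomly chosen
#' absence, with ties counted as one half (mid-rank Mann-Whitney form).
#' One-class genera are undefined (`NA`).
#'
#' @inheritParams tjurR2
#' @return per-genus statistic in [0, 1].
#' @export
aucScore <- function(Y, P) {
  f <- function(y, p) {
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(p)
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  if (is.matrix(Y))
    vapply(seq_len(nrow(Y)), function(j) f(Y[j, ], P[j, ]), numeric(1)) |>
      setNames(rownames(Y))
  else f(Y, P)
}

#' Linear R2 on observed abundance cells
#'
#' Squared Pearson correlation between observed and predicted log
#' abundance over the observed (presence) cells. Undefined (`NA`) when
#' either vector is constant or fewer than two cells are observed.
#'
#' @param zObs observed log abundances (vector or genus x sample matrix,
#'   `NA` where absent).
#' @param zPred predictions, same shape.
#' @return per-genus statistic in [0, 1].
#' @export
r2Linear <- function(zObs, zPred) {
  f <- function(o, p) {
    ok <- !is.na(o) & !is.na(p)
    if (sum(ok) < 2) return(NA_real_)
    if (sd(o[ok]) == 0 || sd(p[ok]) == 0) return(NA_real_)
    cor(o[ok], p[ok])^2
  }
  if (is.matrix(zObs))
    vapply(seq_len(nrow(zObs)), function(j) f(zObs[j, ], zPred[j, ]),
           numeric(1)) |> setNames(rownames(zObs))
  else f(zObs, zPred)
}

#' Explanatory fit metrics for a hurdle pair
#'
#' Predictions from the models fitted to all data (conditioning on the
#' estimated random effects) scored against the training responses.
#'
#' @param fitOcc probit [HurdleFit-class] (or `NULL`).
#' @param fitAb gaussian [HurdleFit-class] (or `NULL`).
#' @param response the [HurdleResponse-class] the models were fitted to.
#' @return data.frame per genus with `tjurR2`, `auc`, `r2`.
#' @export
fitMetrics <- function(fitOcc = NULL, fitAb = NULL, response) {
  out <- data.frame(genus = rownames(response@Y))
  if (!is.null(fitOcc)) {
    P <- predictResponses(fitOcc)
    out$tjurR2 <- tjurR2(response@Y, P[out$genus, , drop = FALSE])
    out$auc <- aucScore(response@Y, P[out$genus, , drop = FALSE])
  }
  if (!is.null(fitAb)) {
    Zhat <- predictResponses(fitAb)
    g <- intersect(out$genus, rownames(Zhat))
    out$r2 <- NA_real_
    out$r2[match(g, out$genus)] <-
      r2Linear(response@Z[g, , drop = FALSE], Zhat[g, , drop = FALSE])
  }
  out
}

#' Variance partition over fixed blocks and random levels
#'
#' Per genus and draw, the variance over samples of each fixed-effect
#' block's contribution (time indicators; log total reads) and each random
#' level's contribution (the genus's squared loadings summed with each
#' factor weighted by its empirical second moment over units, an
#' identified functional under loading/factor rescaling) are normalized to
#' fractions and averaged
#' over the posterior. Group summaries average genus fractions within
#' taxonomic and functional groups (reported in percent).
#'
#' @param fit a [HurdleFit-class].
#' @param traits optional genus trait table for group averages.
#' @return A [VariancePartition-class].
#' @export
variancePartition <- function(fit, traits = NULL) {
  spec <- fit@spec
  D <- dim(fit@beta)[3]; J <- dim(fit@beta)[2]
  comp <- c(names(spec@fixedBlocks), names(spec@randomLevels))
  if (!length(comp)) stop("no variance components in the model")
  acc <- matrix(0, J, length(comp), dimnames = list(spec@genusNames, comp))
  for (d in seq_len(D)) {
    v <- matrix(0, J, length(comp))
    ci <- 1L
    for (bl in spec@fixedBlocks) {
      Xb <- spec@X[, bl, drop = FALSE]
      Fb <- Xb %*% fit@beta[bl, , d, drop = FALSE][, , 1]
      v[, ci] <- apply(Fb, 2, var)
      ci <- ci + 1L
    }
    for (li in seq_along(spec@randomLevels)) {
      Lam <- fit@lambda[[li]][, , d, drop = FALSE]
      dim(Lam) <- dim(fit@lambda[[li]])[1:2]
      Eta <- fit@eta[[li]][, , d, drop = FALSE]
      dim(Eta) <- dim(fit@eta[[li]])[1:2]
      fv <- colMeans(Eta^2)            # factor second moment over units
      v[, ci] <- colSums(Lam^2 * fv)
      ci <- ci + 1L
    }
    tot <- rowSums(v)
    tot[tot == 0] <- 1
    acc <- acc + v / tot
  }
  fr <- acc / D
  gm <- list()
  if (!is.null(traits)) {
    key <- if (!is.null(traits$genus)) traits$genus else rownames(traits)
    tr <- traits[match(rownames(fr), key), , drop = FALSE]
    for (col in intersect(c("taxonomicGroup", "functionalGroup"),
                          colnames(tr))) {
      g <- factor(tr[[col]])
      gm[[col]] <- 100 * t(vapply(levels(g), function(l)
        colMeans(fr[g == l, , drop = FALSE]),
        numeric(ncol(fr))))
    }
  }
  new("VariancePartition", fractions = fr, groupMeans = gm)
}

#' Random fold assignment and predictive cross-validation
#'
#' Samples (the cross-validation units) are assigned uniformly at random
#' to folds; each fold is predicted from models fitted to the remaining
#' folds, with the latent factors of units unseen in training marginalized
#' (the sample level always is). Held-out predictions are assembled over
#' all samples and scored per genus.
#'
#' @param response a prevalence-filtered [HurdleResponse-class].
#' @param traits optional trait table.
#' @param schedule MCMC schedule used for each fold's fits.
#' @param nFolds number of folds (default 2).
#' @param seed integer seed (fold assignment and fits).
#' @param fitAbundanceArm also fit and score the abundance arm.
#' @param ... passed to [makeModelSpec()].
#' @return list with `metrics` (per-genus data.frame), `P` and `Zhat`
#'   (assembled held-out predictions) and `folds` (assignment).
#' @export
crossValidate <- function(response, traits = NULL,
                          schedule = McmcSchedule(), nFolds = 2,
                          seed = 1, fitAbundanceArm = TRUE, ...) {
  set.seed(seed)
  n <- ncol(response@Y)
  folds <- sample(rep_len(seq_len(nFolds), n))
  genus <- rownames(response@Y)
  P <- matrix(NA_real_, length(genus), n,
              dimnames = dimnames(response@Y))
  Zhat <- P
  for (f in seq_len(nFolds)) {
    tr <- folds != f; te <- folds == f
    sTr <- droplevels(response@samples[tr, , drop = FALSE])
    sTe <- response@samples[te, , drop = FALSE]
    respTr <- new("HurdleResponse",
                  Y = response@Y[, tr, drop = FALSE],
                  Z = response@Z[, tr, drop = FALSE],
                  logTotalReads = response@logTotalReads[tr],
                  samples = sTr)
    fo <- fitOccurrence(respTr, schedule = schedule, seed = seed + f,
                        samples = sTr, traits = traits, ...)
    # centre held-out logReads on the training centre
    Xte <- cbind("(Intercept)" = 1,
                 timeT2 = as.numeric(as.integer(sTe$timepoint) == 2L),
                 timeT3 = as.numeric(as.integer(sTe$timepoint) == 3L),
                 logReads = log(sTe$totalReads) -
                   mean(log(sTr$totalReads)))
    ul <- lapply(fo@spec@randomLevels, function(l)
      switch(l$name, sample = sTe$sample, sTe[[l$name]]))
    P[, te] <- t(.predictCells(fo, X = Xte, unitLabels = ul,
                               marginalizeLevels = "sample"))
    if (fitAbundanceArm) {
      okG <- rowSums(!is.na(response@Z[, tr, drop = FALSE])) >= 2
      respAb <- new("HurdleResponse",
                    Y = response@Y[okG, tr, drop = FALSE],
                    Z = response@Z[okG, tr, drop = FALSE],
                    logTotalReads = response@logTotalReads[tr],
                    samples = sTr)
      fa <- fitAbundance(respAb, schedule = schedule, seed = seed + 50 + f,
                         samples = sTr, traits = if (!is.null(traits))
                           traits else NULL, ...)
      Zh <- t(.predictCells(fa, X = Xte, unitLabels = ul,
                            marginalizeLevels = "sample"))
      Zhat[okG, te] <- Zh
    }
  }
  metrics <- data.frame(genus = genus,
                        tjurR2 = tjurR2(response@Y, P),
                        auc = aucScore(response@Y, P))
  if (fitAbundanceArm)
    metrics$r2 <- r2Linear(response@Z, Zhat)
  list(metrics = metrics, P = P, Zhat = Zhat, folds = folds)
}

#' Fixed-effect seasonal occurrence predictions and trend calls
#'
#' Using only the fixed-effect part of the occurrence model, the
#' occurrence probability of each genus is predicted for the three time
#' points (log total reads fixed at its sample mean, i.e. zero on the
#' centred scale) for every posterior draw. `pIncrease` is the posterior
#' probability that the August probability exceeds the June one; a genus
#' is called increasing when `pIncrease >= threshold` and decreasing when
#' `pIncrease <= 1 - threshold`.
#'
#' @param fit probit [HurdleFit-class].
#' @param threshold posterior-probability threshold (default 0.95).
#' @param atLogReads value of the centred log-reads covariate (default 0,
#'   the sample mean).
#' @return A [SeasonalPrediction-class].
#' @export
predictSeasonal <- function(fit, threshold = 0.95, atLogReads = 0) {
  if (fit@family != "probit")
    stop("seasonal occurrence predictions require the probit arm")
  need <- c("(Intercept)", "timeT2", "timeT3", "logReads")
  if (!all(need %in% dimnames(fit@beta)[[1]]))
    stop("missing season coefficients in the fit")
  D <- dim(fit@beta)[3]; J <- dim(fit@beta)[2]
  b0 <- fit@beta["(Intercept)", , ]                     # J x D
  bR <- fit@beta["logReads", , ] * atLogReads
  eta1 <- b0 + bR
  eta2 <- eta1 + fit@beta["timeT2", , ]
  eta3 <- eta1 + fit@beta["timeT3", , ]
  occ <- array(NA_real_, c(D, J, 3),
               dimnames = list(NULL, dimnames(fit@beta)[[2]],
                               c("T1", "T2", "T3")))
  occ[, , 1] <- t(pnorm(eta1)); occ[, , 2] <- t(pnorm(eta2))
  occ[, , 3] <- t(pnorm(eta3))
  # exact ties (e.g. a degenerate August coefficient) count one half
  pInc <- colMeans(occ[, , 3] > occ[, , 1]) +
    0.5 * colMeans(occ[, , 3] == occ[, , 1])
  call <- ifelse(pInc >= threshold, "increase",
                 ifelse(pInc <= 1 - threshold, "decrease", "none"))
  new("SeasonalPrediction", occProb = occ,
      probMean = apply(occ, c(2, 3), mean),
      pIncrease = pInc, trendCall = call, threshold = threshold)
}

#' Temporal co-occurrence matrix Omega with posterior sign calls
#'
#' For each posterior draw, the element for genus pair (j1, j2) is
#' `betaT2[j1] * betaT2[j2] + betaT3[j1] * betaT3[j2]`, the inner product
#' of the two genera's seasonal responses (June as reference). Positive
#' elements mark pairs that shift into the same part of the season. Sign
#' calls are made where the posterior probability of a positive (or
#' negative) element reaches the threshold.
#'
#' @param fit probit [HurdleFit-class], or a list with genus x draw
#'   matrices `betaT2` and `betaT3`.
#' @param threshold posterior-probability threshold (default 0.90).
#' @return An [OmegaSummary-class].
#' @export
omegaMatrix <- function(fit, threshold = 0.90) {
  if (is(fit, "HurdleFit")) {
    bT2 <- fit@beta["timeT2", , , drop = FALSE]
    bT3 <- fit@beta["timeT3", , , drop = FALSE]
    dim(bT2) <- dim(bT3) <- dim(fit@beta)[2:3]
    genus <- dimnames(fit@beta)[[2]]
  } else {
    bT2 <- as.matrix(fit$betaT2); bT3 <- as.matrix(fit$betaT3)
    genus <- rownames(bT2)
  }
  J <- nrow(bT2); D <- ncol(bT2)
  if (J < 2) stop("need at least 2 genera")
  mean <- matrix(0, J, J); pos <- matrix(0, J, J)
  neg <- matrix(0, J, J)
  for (d in seq_len(D)) {
    Om <- tcrossprod(bT2[, d]) + tcrossprod(bT3[, d])
    mean <- mean + Om
    pos <- pos + (Om > 0)
    neg <- neg + (Om < 0)
  }
  mean <- mean / D; pos <- pos / D; neg <- neg / D
  sign <- matrix(0L, J, J)
  sign[pos >= threshold] <- 1L
  sign[neg >= threshold] <- -1L
  dimnames(mean) <- dimnames(pos) <- dimnames(neg) <- dimnames(sign) <-
    list(genus, genus)
  new("OmegaSummary", omegaMean = mean, pPos = pos, pNeg = neg,
      signCall = sign, threshold = threshold)
}

#' Unconditional expected relative abundance under the hurdle pair
#'
#' Combines the two arms: the occurrence probability times the log-normal
#' mean `exp(mu + sigma2/2)` of abundance given presence, using posterior
#' means. The conditional (presence-only) predictions used for R2 live in
#' [predictResponses()].
#'
#' @param fitOcc probit arm fit.
#' @param fitAb gaussian arm fit.
#' @return genus x sample matrix of expected RRA.
#' @export
expectedAbundance <- function(fitOcc, fitAb) {
  P <- predictResponses(fitOcc)
  Zm <- predictResponses(fitAb)
  s2 <- rowMeans(fitAb@sigma2)
  g <- intersect(rownames(P), rownames(Zm))
  P[g, , drop = FALSE] *
    exp(Zm[g, , drop = FALSE] + s2[match(g, fitAb@spec@genusNames)] / 2)
}
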