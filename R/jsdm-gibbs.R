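## Gibbs sampler for one arm of the hurdle JSDM pair.
##
## Occurrence arm: multivariate probit via truncated-normal data
## augmentation (residual variance fixed at 1). Abundance arm: Gaussian
## likelihood on the observed (presence) cells only, per-genus residual
## variance. Both arms share the hierarchical structure: genus coefficients
## shrunk towards a trait-level regression with an inverse-Wishart
## coefficient covariance, and crossed latent-factor random effects with
## multiplicative-gamma loading shrinkage; the site level may carry an
## exponential spatial kernel whose range is sampled over a discrete grid.
##
## Update order within a sweep: liabilities -> genus coefficients -> trait
## regression -> coefficient covariance -> per level (factors, spatial
## range, loadings, shrinkage) -> residual variances.

# truncated standard-normal-location draws: z ~ N(mu, 1) given sign(y)
.truncNorm <- function(mu, y) {
  pLo <- pnorm(-mu)
  u <- runif(length(mu))
  uu <- ifelse(y == 1, pLo + u * (1 - pLo), u * pLo)
  uu <- pmin(pmax(uu, 1e-12), 1 - 1e-12)
  mu + qnorm(uu)
}

# draw from N(P^-1 b, P^-1) given precision P and linear term b
.mvnPrec <- function(P, b) {
  U <- chol(P)
  m <- backsolve(U, backsolve(U, b, transpose = TRUE))
  m + backsolve(U, rnorm(length(b)))
}

# spatial-range grid and per-grid-point kernel Cholesky factors
.alphaGridSetup <- function(coords, priors) {
  dmax <- max(dist(coords))
  grid <- c(0, seq(dmax / priors$nAlphaGrid, dmax * priors$alphaMaxFrac,
                   length.out = priors$nAlphaGrid))
  w <- c(priors$alphaZeroWeight,
         rep((1 - priors$alphaZeroWeight) / priors$nAlphaGrid,
             priors$nAlphaGrid))
  U <- nrow(coords)
  chols <- lapply(grid, function(a) {
    K <- .expKernel(coords, a)
    chol(K + 1e-8 * diag(U))
  })
  list(grid = grid, logw = log(w), chols = chols,
       logdet = vapply(chols, function(ch) 2 * sum(log(diag(ch))),
                       numeric(1)))
}

# one chain of the Gibbs sampler; returns retained draws
.gibbsChain <- function(Yobs, Zobs, family, spec, schedule, chainSeed) {
  set.seed(chainSeed)
  X <- spec@X; Tr <- spec@traitDesign; pri <- spec@priors
  n <- nrow(X); p <- ncol(X); J <- length(spec@genusNames)
  q <- ncol(Tr)
  probit <- family == "probit"
  if (probit) {
    mask <- matrix(TRUE, n, J)
    Zl <- ifelse(Yobs == 1, 0.5, -0.5)
  } else {
    mask <- !is.na(Zobs)
    Zl <- ifelse(mask, Zobs, 0)
  }
  nObs <- colSums(mask)
  Xt <- t(X); XtX <- crossprod(X)
  XtXobs <- if (!probit)
    lapply(seq_len(J), function(j) crossprod(X[mask[, j], , drop = FALSE]))
  TtT <- crossprod(Tr)
  nu0 <- p + pri$f0; Psi0 <- pri$V0scale * diag(p)

  levels <- spec@randomLevels
  L <- length(levels)
  lv <- lapply(levels, function(l) {
    ui <- as.integer(l$units); U <- nlevels(l$units); nf <- l$nFactors
    st <- list(ui = ui, U = U, nf = nf, spatial = l$spatial,
               Eta = matrix(rnorm(U * nf, sd = 0.1), U, nf),
               Lambda = matrix(rnorm(nf * J, sd = 0.1), nf, J),
               phi = matrix(1, nf, J), delta = rep(1, nf),
               alphaIdx = 1L)
    if (l$spatial) st$ag <- .alphaGridSetup(l$coords, pri)
    st$contrib <- st$Eta[ui, , drop = FALSE] %*% st$Lambda
    st
  })

  B <- matrix(0, p, J)
  Gamma <- matrix(0, q, p)
  V <- diag(p); Vinv <- diag(p)
  sigma2 <- rep(1, J)

  ret <- retainedDraws(schedule)$perChain
  out <- list(beta = array(NA_real_, c(p, J, ret)),
              gamma = array(NA_real_, c(q, p, ret)),
              V = array(NA_real_, c(p, p, ret)),
              sigma2 = matrix(NA_real_, J, ret),
              lambda = lapply(lv, function(s)
                array(NA_real_, c(s$nf, J, ret))),
              eta = lapply(lv, function(s)
                array(NA_real_, c(s$U, s$nf, ret))),
              alpha = lapply(lv, function(s) rep(NA_real_, ret)))
  kept <- 0L

  ranefTotal <- function() {
    R <- matrix(0, n, J)
    for (s in lv) R <- R + s$contrib
    R
  }

  for (it in seq_len(schedule@nIterations)) {
    ranef <- ranefTotal()
    mu <- X %*% B + ranef

    ## 1. latent liabilities (probit only)
    if (probit) Zl <- matrix(.truncNorm(mu, Yobs), n, J)

    ## 2. genus coefficients
    MuB <- t(Tr %*% Gamma)                       # p x J prior means
    Rb <- Zl - ranef
    if (probit) {
      A <- XtX + Vinv
      Uc <- chol(A)
      rhs <- Xt %*% Rb + Vinv %*% MuB
      Bm <- backsolve(Uc, backsolve(Uc, rhs, transpose = TRUE))
      B <- Bm + backsolve(Uc, matrix(rnorm(p * J), p, J))
    } else {
      for (j in seq_len(J)) {
        mj <- mask[, j]
        A <- XtXobs[[j]] / sigma2[j] + Vinv
        bj <- crossprod(X[mj, , drop = FALSE], Rb[mj, j]) / sigma2[j] +
          Vinv %*% MuB[, j]
        B[, j] <- .mvnPrec(A, bj)
      }
    }

    ## 3. trait regression
    Bt <- t(B)
    P <- kronecker(Vinv, TtT) + diag(q * p) / pri$gammaVar
    rhs <- as.vector(crossprod(Tr, Bt) %*% Vinv)
    Gamma <- matrix(.mvnPrec(P, rhs), q, p)

    ## 4. coefficient covariance
    E <- Bt - Tr %*% Gamma
    S <- Psi0 + crossprod(E)
    W <- rWishart(1, nu0 + J, chol2inv(chol(S)))[, , 1]
    V <- chol2inv(chol(W)); Vinv <- W

    ## 5. random levels
    XB <- X %*% B
    Wt <- if (probit) mask * 1 else
      sweep(mask * 1, 2, sigma2, "/")            # precision weights
    for (li in seq_len(L)) {
      s <- lv[[li]]
      other <- matrix(0, n, J)
      for (k in seq_len(L)) if (k != li) other <- other + lv[[k]]$contrib
      R <- Zl - XB - other
      R[!mask] <- 0
      nf <- s$nf; U <- s$U
      WR <- rowsum(Wt * R, s$ui)                 # U x J
      Wu <- rowsum(Wt, s$ui)                     # U x J

      ## 5a. latent factors
      Lam <- s$Lambda
      if (s$spatial) {
        ch <- s$ag$chols[[s$alphaIdx]]
        Kinv <- chol2inv(ch)
        Pf <- kronecker(diag(nf), Kinv)
        bf <- numeric(U * nf)
        for (u in seq_len(U)) {
          Pu <- Lam %*% (Wu[u, ] * t(Lam))
          idx <- u + (seq_len(nf) - 1L) * U
          Pf[idx, idx] <- Pf[idx, idx] + Pu
          bf[idx] <- Lam %*% WR[u, ]
        }
        s$Eta <- matrix(.mvnPrec(Pf, bf), U, nf)
        ## 5b. spatial range over the grid
        ll <- s$ag$logw
        for (g in seq_along(s$ag$grid)) {
          chg <- s$ag$chols[[g]]
          qf <- sum(backsolve(chg, s$Eta, transpose = TRUE)^2)
          ll[g] <- ll[g] - 0.5 * qf - 0.5 * nf * s$ag$logdet[g]
        }
        pr <- exp(ll - max(ll))
        s$alphaIdx <- sample.int(length(pr), 1L, prob = pr)
      } else if (probit) {
        # uniform unit weights: the conditional precision depends only on
        # the unit's sample count, so units batch by count
        LLt <- tcrossprod(Lam)
        RHS <- WR %*% t(Lam)                     # U x nf
        cnt <- tabulate(s$ui, U)
        for (m in unique(cnt)) {
          rows <- which(cnt == m)
          Uc <- chol(diag(nf) + m * LLt)
          Mn <- t(backsolve(Uc, backsolve(Uc, t(RHS[rows, , drop = FALSE]),
                                          transpose = TRUE)))
          Uinv <- backsolve(Uc, diag(nf))
          s$Eta[rows, ] <- Mn +
            matrix(rnorm(length(rows) * nf), length(rows), nf) %*% t(Uinv)
        }
      } else {
        Inf_ <- diag(nf)
        for (u in seq_len(U)) {
          Pu <- Inf_ + Lam %*% (Wu[u, ] * t(Lam))
          s$Eta[u, ] <- .mvnPrec(Pu, Lam %*% WR[u, ])
        }
      }

      ## 5c. loadings with multiplicative-gamma shrinkage
      H <- s$Eta[s$ui, , drop = FALSE]           # n x nf
      tauh <- cumprod(s$delta)
      for (j in seq_len(J)) {
        wj <- Wt[, j]
        Pj <- crossprod(H, wj * H) + diag(s$phi[, j] * tauh, nf)
        bj <- crossprod(H, wj * R[, j])
        s$Lambda[, j] <- .mvnPrec(Pj, bj)
      }
      ## local precisions
      lam2 <- s$Lambda^2
      s$phi <- matrix(rgamma(nf * J, shape = (pri$nu + 1) / 2,
                             rate = (pri$nu + tauh * lam2) / 2), nf, J)
      ## column multipliers
      for (h in seq_len(nf)) {
        tauExcl <- cumprod(s$delta) / s$delta[h]
        tauExcl[seq_len(h - 1L)] <- 0            # only columns >= h count
        shape <- (if (h == 1L) pri$a1 else pri$a2) +
          J * (nf - h + 1L) / 2
        rate <- 1 + 0.5 * sum(tauExcl * rowSums(s$phi * lam2))
        s$delta[h] <- rgamma(1, shape = shape, rate = rate)
      }
      s$contrib <- s$Eta[s$ui, , drop = FALSE] %*% s$Lambda
      lv[[li]] <- s
    }

    ## 6. residual variances (gaussian arm)
    if (!probit) {
      resid <- Zl - XB - ranefTotal()
      for (j in seq_len(J)) {
        ss <- sum(resid[mask[, j], j]^2)
        sigma2[j] <- 1 / rgamma(1, shape = pri$aSigma + nObs[j] / 2,
                                rate = pri$bSigma + ss / 2)
      }
    }

    ## retention
    if (it > schedule@nBurnin &&
        (it - schedule@nBurnin) %% schedule@thin == 0L) {
      kept <- kept + 1L
      out$beta[, , kept] <- B
      out$gamma[, , kept] <- Gamma
      out$V[, , kept] <- V
      out$sigma2[, kept] <- sigma2
      for (li in seq_len(L)) {
        out$lambda[[li]][, , kept] <- lv[[li]]$Lambda
        out$eta[[li]][, , kept] <- lv[[li]]$Eta
        out$alpha[[li]][kept] <- if (lv[[li]]$spatial)
          lv[[li]]$ag$grid[lv[[li]]$alphaIdx] else NA_real_
      }
    }
  }
  out
}

# run all chains and assemble a HurdleFit
.fitArm <- function(Yobs, Zobs, family, spec, schedule, seed) {
  validObject(schedule)
  chains <- lapply(seq_len(schedule@nChains), function(ch)
    .gibbsChain(Yobs, Zobs, family, spec, schedule,
                chainSeed = seed + ch - 1L))
  ret <- retainedDraws(schedule)
  bindLast <- function(get) {
    arrs <- lapply(chains, get)
    d <- dim(arrs[[1]])
    arr <- array(NA_real_, c(d[-length(d)], ret$total))
    for (i in seq_along(arrs)) {
      idx <- (i - 1L) * ret$perChain + seq_len(ret$perChain)
      if (length(d) == 3L) arr[, , idx] <- arrs[[i]]
      else arr[, idx] <- arrs[[i]]
    }
    arr
  }
  L <- length(spec@randomLevels)
  fit <- new("HurdleFit", family = family,
             beta = bindLast(function(c) c$beta),
             gamma = bindLast(function(c) c$gamma),
             V = bindLast(function(c) c$V),
             sigma2 = bindLast(function(c) c$sigma2),
             lambda = if (L) lapply(seq_len(L), function(li)
               bindLast(function(c) c$lambda[[li]])) else list(),
             eta = if (L) lapply(seq_len(L), function(li)
               bindLast(function(c) c$eta[[li]])) else list(),
             alpha = if (L) lapply(seq_len(L), function(li)
               unlist(lapply(chains, function(c) c$alpha[[li]])))
             else list(),
             chain = rep(seq_len(schedule@nChains),
                         each = ret$perChain),
             spec = spec, schedule = schedule)
  names(fit@lambda) <- names(fit@eta) <- names(fit@alpha) <-
    names(spec@randomLevels)
  dimnames(fit@beta) <- list(colnames(spec@X), spec@genusNames, NULL)
  fit
}
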