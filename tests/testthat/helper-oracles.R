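# Independent brute-force oracles for the four marginal likelihoods.
# Deliberately share no code with the package internals: plain Simpson /
# trapezoid quadrature on dense grids, subset expansion for the mixture.

simpsonW <- function(n, h) {
  w <- rep(c(2, 4), length.out = n); w[1] <- w[n] <- 1
  w * h / 3
}

oracleLamGrid <- function(post, n = 4001) {
  lo <- qgamma(1e-12, post@shape, rate = post@rate)
  hi <- qgamma(1 - 1e-12, post@shape, rate = post@rate)
  seq(max(lo, 1e-10), hi, length.out = n)
}

# log integral of prod_j Poi(y_j | lam) against the gamma posterior density
oracleCompMass <- function(ys, post, n = 4001) {
  lam <- oracleLamGrid(post, n)
  lf <- dgamma(lam, post@shape, rate = post@rate, log = TRUE)
  for (yy in ys) lf <- lf + dpois(yy, lam, log = TRUE)
  m <- max(lf)
  m + log(sum(simpsonW(n, lam[2] - lam[1]) * exp(lf - m)))
}

oracleSingle <- function(y, post) oracleCompMass(y, post)

# mixture marginal by the distributive expansion over component assignments:
# the alpha integral is an exact Beta function, the rate integrals are 1-D
oracleMixture <- function(y, postA, postB) {
  m <- length(y)
  tot <- -Inf
  for (mask in 0:(2^m - 1)) {
    S <- which(bitwAnd(mask, 2^(0:(m - 1))) > 0)
    lt <- lbeta(length(S) + 1, m - length(S) + 1) +
      oracleCompMass(y[S], postA) +
      oracleCompMass(y[setdiff(seq_len(m), S)], postB)
    tot <- if (is.finite(tot)) max(tot, lt) + log1p(exp(-abs(tot - lt)))
           else lt
  }
  tot
}

# intermediate / outside marginals: 2-D Simpson over the rate-pair
# posteriors, with the lamAB integral taken from a fine cumulative trapezoid
# of lam^(-1/2) * lik(lam)
oracleRegion <- function(y, postA, postB,
                         type = c("intermediate", "outside"), U = 10,
                         nPost = 601, nFine = 60001) {
  type <- match.arg(type)
  top <- max(qgamma(1 - 1e-12, postA@shape, rate = postA@rate),
             qgamma(1 - 1e-12, postB@shape, rate = postB@rate))
  fmax <- if (type == "outside") U * top * 1.001 else top * 1.001
  lam <- seq(1e-9, fmax, length.out = nFine)
  lg <- -0.5 * log(lam)
  for (yy in y) lg <- lg + dpois(yy, lam, log = TRUE)
  mx <- max(lg)
  g <- exp(lg - mx)
  G <- c(0, cumsum((g[-1] + g[-nFine]) / 2 * (lam[2] - lam[1])))
  Gf <- approxfun(lam, G, rule = 2)
  la <- oracleLamGrid(postA, nPost); lb <- oracleLamGrid(postB, nPost)
  wa <- simpsonW(nPost, la[2] - la[1]) *
    dgamma(la, postA@shape, rate = postA@rate)
  wb <- simpsonW(nPost, lb[2] - lb[1]) *
    dgamma(lb, postB@shape, rate = postB@rate)
  LO <- outer(la, lb, pmin); HI <- outer(la, lb, pmax)
  I <- if (type == "intermediate") {
    (Gf(HI) - Gf(LO)) / (2 * (sqrt(HI) - sqrt(LO)))
  } else {
    (Gf(LO) + Gf(pmin(U * HI, fmax)) - Gf(HI)) /
      (2 * sqrt(LO) + 2 * (sqrt(U * HI) - sqrt(HI)))
  }
  I[!is.finite(I)] <- 0
  log(as.numeric(t(wa) %*% I %*% wb)) + mx
}

# quadrature presets used across tests
quadFast <- function() mixtureQuad(nAlpha = 101, nDraws = 2000)
quadOracle <- function() mixtureQuad(nDraws = 10000, rateMethod = "quantile")
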