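# small builders used by several test files

makeTriplet <- function(lamA = 20, lamB = 5, nSingle = 21, nAB = 18,
                        regime = c("mixture", "single", "intermediate",
                                   "outside"),
                        alpha = 0.5, seed = 1, unit = "u1", key = "c1") {
  regime <- match.arg(regime)
  spikemux:::withSeed(seed, {
    muAB <- switch(regime,
                   single = lamA,
                   intermediate = (lamA + lamB) / 2,
                   outside = 1.5 * max(lamA, lamB),
                   mixture = NA)
    cAB <- if (regime == "mixture") {
      fromA <- runif(nAB) < alpha
      rpois(nAB, ifelse(fromA, lamA, lamB))
    } else rpois(nAB, muAB)
    Triplet(unit, key, rpois(nSingle, lamA), rpois(nSingle, lamB), cAB)
  })
}

swapTripletLabels <- function(t) {
  Triplet(unitId(t), conditionKey(t),
          countsA = countsB(t), countsB = countsA(t),
          countsAB = countsAB(t),
          presA = t@presB, presB = t@presA, presAB = t@presAB)
}

flatTrace <- function(n = 100, rate = 500, id = "p1") {
  eyeTrace(id, rate, rep(0.1, n), rep(-0.05, n))
}

# trace with a 1 degree step over one sample on a quiet baseline
stepTrace <- function(n = 100, rate = 500, at = 50, amp = 1, noise = 1e-4,
                      seed = 5, id = "p1") {
  spikemux:::withSeed(seed, {
    x <- rnorm(n, 0, noise)
    x[at:n] <- x[at:n] + amp
    eyeTrace(id, rate, x, rnorm(n, 0, noise))
  })
}
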