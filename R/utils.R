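# internal numerical helpers

logSumExp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

logMeanExp <- function(x) logSumExp(x) - log(length(x))

## log(P(q1 < X <= q2)) for X ~ Gamma(shape, rate), stable in both tails.
## Vectorized over q1, q2.
logPgammaDiff <- function(q1, q2, shape, rate) {
  stopifnot(length(q1) == length(q2))
  l2 <- stats::pgamma(q2, shape, rate = rate, lower.tail = TRUE, log.p = TRUE)
  l1 <- stats::pgamma(q1, shape, rate = rate, lower.tail = TRUE, log.p = TRUE)
  u1 <- stats::pgamma(q1, shape, rate = rate, lower.tail = FALSE, log.p = TRUE)
  u2 <- stats::pgamma(q2, shape, rate = rate, lower.tail = FALSE, log.p = TRUE)
  res <- numeric(length(q1))
  low <- l2 <= log(0.5)         # mass below q2 is small: lower-tail pair stable
  res[low] <- l2[low] + log1p(-exp(pmin(l1[low] - l2[low], 0)))
  res[!low] <- u1[!low] + log1p(-exp(pmin(u2[!low] - u1[!low], 0)))
  res[q1 >= q2 | is.nan(res)] <- -Inf
  res
}

## elementwise log(exp(a) + exp(b)) with -Inf guards
logAddExp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(-abs(a - b)))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

## Evaluate expr under a temporary RNG state seeded with `seed` (NULL = leave
## the RNG stream alone). Restores the caller's .Random.seed afterwards.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a reproducible child seed from a base seed (kept below 2^31).
childSeed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000000L) * 1000L + (as.integer(k) %% 1000L)
}

configHash <- function(x) rlang::hash(x)

.checkCounts <- function(x, what = "counts") {
  if (!length(x)) stop(what, " must be non-empty", call. = FALSE)
  if (anyNA(x) || any(x < 0) || any(x != floor(x)))
    stop(what, " must be non-negative integers", call. = FALSE)
  as.integer(x)
}
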