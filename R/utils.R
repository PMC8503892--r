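# shared small numerics

geomMean <- function(x) exp(mean(log(x)))

rowVars <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1L)
}

# Exact 1-D two-level split minimizing within-group sum of squares.
# Returns NULL when all values are equal; otherwise a list with the logical
# `high` membership and the `gap` between the two level means.
splitTwoLevels <- function(x) {
  if (length(unique(x)) < 2L) return(NULL)
  o <- order(x)
  xs <- x[o]
  n <- length(xs)
  csum <- cumsum(xs)
  tot <- csum[n]
  k <- seq_len(n - 1L)
  # within-SS decomposition: total SS minus between-SS of the split
  between <- csum[k]^2 / k + (tot - csum[k])^2 / (n - k) - tot^2 / n
  kbest <- k[which.max(between)]
  cut <- (xs[kbest] + xs[kbest + 1L]) / 2
  lowMean <- csum[kbest] / kbest
  highMean <- (tot - csum[kbest]) / (n - kbest)
  list(high = x > cut, gap = highMean - lowMean)
}

# run expr with a temporary RNG state seeded from `seed`,
# restoring the caller's stream afterwards
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
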