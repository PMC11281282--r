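# Independent brute-force oracles used to cross-check the package's own
# implementations. Deliberately written as plain loops over the textbook
# update formulas, sharing no code with the package.

# Fuzzy c-means by alternating optimization from many random starts; returns
# the best (lowest) converged objective.
fcmRestartOracle <- function(x, c = 2, m = 2, restarts = 50, tol = 1e-12,
                             maxIter = 5000, seed = 1) {
  set.seed(seed)
  n <- length(x)
  best <- Inf
  for (r in seq_len(restarts)) {
    v <- sort(sample(unique(x), c))
    for (it in seq_len(maxIter)) {
      u <- matrix(0, n, c)
      for (i in seq_len(n)) {
        d <- abs(x[i] - v)
        if (any(d == 0)) {
          u[i, which(d == 0)[1]] <- 1
        } else {
          inv <- d^(-2 / (m - 1))
          u[i, ] <- inv / sum(inv)
        }
      }
      vNew <- numeric(c)
      for (k in seq_len(c)) {
        w <- u[, k]^m
        vNew[k] <- sum(w * x) / sum(w)
      }
      if (max(abs(vNew - v)) < tol) {
        v <- vNew
        break
      }
      v <- vNew
    }
    obj <- 0
    for (i in seq_len(n)) {
      for (k in seq_len(c)) obj <- obj + u[i, k]^m * (x[i] - v[k])^2
    }
    if (obj < best) best <- obj
  }
  best
}

# Jaccard overlap of two logical arrays.
jaccard <- function(a, b) sum(a & b) / sum(a | b)

# One small high-SNR synthetic image and its end-to-end estimate.
estimateFraction <- function(targetFraction, seed, shape = c(512L, 512L)) {
  out <- simulateFiberImage(FiberImageParams(
    shape = shape, targetFraction = targetFraction, seed = as.integer(seed)))
  est <- extractFibers(out$image)
  c(truth = percentFiberVolume(out$truth),
    estimate = est$percentFiberVolume)
}
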