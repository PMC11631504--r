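# Shared fixture builders; all randomness is seeded per call.

# small standardized training set (p > n by default)
standardizedFixture <- function(n = 20, p = 50, seed = 101) {
  X <- simulateGenotypes(n, p, seed = seed)
  ph <- simulatePhenotype(X, nQtl = max(1L, p %/% 10L), h2Target = 0.5,
                          seed = seed + 1L)
  st <- fitStandardizer(X, ph$y)
  sd <- applyStandardizer(X, st, ph$y)
  list(X = X, y = ph$y, stats = st, Xs = sd$Xs, ys = sd$ys,
       truth = ph$truth)
}

# dense gaussian design, useful for solver oracles
gaussianFixture <- function(n, p, seed, noise = 0.5) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- rnorm(p)
  y <- as.numeric(X %*% beta) + rnorm(n, sd = noise)
  list(X = X, y = y, beta = beta)
}

# direct closed-form ridge on centered data under the 1/(2n) objective
ridgeOracle <- function(X, y, lambda) {
  n <- nrow(X)
  xm <- colMeans(X)
  Xc <- sweep(X, 2L, xm, "-")
  yc <- y - mean(y)
  b <- solve(crossprod(Xc) / n + lambda * diag(ncol(X)),
             crossprod(Xc, yc) / n)
  as.numeric(b)
}
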