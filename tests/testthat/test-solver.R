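test_that("ridge limits: OLS at lambda = 0, zero at huge lambda, zero intercept", {
  gx <- gaussianFixture(40, 8, seed = 61)
  f0 <- fitPath(gx$X, gx$y, 0, alpha = 0)
  ols <- lm.fit(cbind(1, gx$X), gx$y)$coefficients
  expect_equal(unname(coef(f0)[, 1]), unname(ols[-1]), tolerance = 1e-8)
  expect_equal(f0@intercepts[1], unname(ols[1]), tolerance = 1e-8)

  fx <- standardizedFixture(seed = 63)
  fbig <- fitPath(fx$Xs, fx$ys, 1e6, alpha = 0)
  expect_lt(max(abs(coef(fbig))), 1e-6)
  # on standardized data the intercept is analytically zero
  fstd <- fitPath(fx$Xs, fx$ys, c(10, 1, 0.1), alpha = 0)
  expect_lt(max(abs(fstd@intercepts)), 1e-10)
})

test_that("coordinate descent matches the closed-form ridge solution", {
  gx <- gaussianFixture(30, 10, seed = 67)
  fcd <- fitPath(gx$X, gx$y, 0.7, alpha = 0, engine = "cd", tol = 1e-10)
  expect_equal(unname(coef(fcd)[, 1]), ridgeOracle(gx$X, gx$y, 0.7),
               tolerance = 1e-8)

  # property: 50 random instances across shapes, including p > n
  set.seed(71)
  worst <- 0
  for (i in 1:50) {
    n <- sample(10:60, 1)
    p <- sample(2:120, 1)
    gx <- gaussianFixture(n, p, seed = 1000 + i, noise = 1)
    lam <- runif(1, 0.05, 2)
    fcd <- fitPath(gx$X, gx$y, lam, alpha = 0, engine = "cd", tol = 1e-10)
    fex <- fitPath(gx$X, gx$y, lam, alpha = 0, engine = "exact")
    worst <- max(worst, max(abs(coef(fcd) - coef(fex))))
  }
  expect_lt(worst, 1e-6)
})

test_that("lasso solution matches brute-force objective minimization", {
  set.seed(73)
  X <- matrix(rnorm(24), 12, 2)
  y <- 1.2 * X[, 1] - 0.4 * X[, 2] + rnorm(12, sd = 0.3)
  lam <- 0.15
  f <- fitPath(X, y, lam, alpha = 1, tol = 1e-12)
  # exhaustive search over a fine beta lattice
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
  grid <- seq(-2, 2, by = 0.005)
  obj <- function(b1, b2)
    mean((yc - Xc[, 1] * b1 - Xc[, 2] * b2)^2) / 2 + lam * (abs(b1) + abs(b2))
  vals <- outer(grid, grid, Vectorize(obj))
  best <- which(vals == min(vals), arr.ind = TRUE)[1, ]
  expect_equal(unname(coef(f)[, 1]), c(grid[best[1]], grid[best[2]]),
               tolerance = 0.01)
})

test_that("each coordinate-descent sweep decreases the objective", {
  gx <- gaussianFixture(25, 40, seed = 79)
  for (a in c(0, 0.5, 1)) {
    f <- fitPath(gx$X, gx$y, c(1, 0.3, 0.05), alpha = a, engine = "cd",
                 trackObjective = TRUE)
    for (tr in f@objective) {
      if (length(tr) > 1) expect_true(all(diff(tr) <= 1e-12))
    }
  }
})

test_that("ridge coefficient norms shrink monotonically with lambda", {
  fx <- standardizedFixture(n = 30, p = 70, seed = 83)
  g <- conventionalGrid(fx$Xs, fx$ys)
  f <- fitPath(fx$Xs, fx$ys, g, alpha = 0)
  norms <- sqrt(colSums(coef(f)^2))
  # path is descending in lambda, so norms must be non-decreasing
  expect_true(all(diff(norms) >= -1e-12))
})

test_that("warm and cold starts converge to the same path", {
  gx <- gaussianFixture(30, 15, seed = 89)
  lams <- c(2, 0.8, 0.3, 0.1)
  for (a in c(0.3, 1)) {
    fw <- fitPath(gx$X, gx$y, lams, alpha = a, tol = 1e-10)
    fc <- fitPath(gx$X, gx$y, lams, alpha = a, tol = 1e-10,
                  warmStart = FALSE)
    expect_equal(coef(fw), coef(fc), tolerance = 1e-6)
  }
})

test_that("the per-observation objective maps to the textbook PRSS", {
  # minimizing (1/2n)RSS + (lambda/2)||b||^2 equals minimizing
  # RSS + n*lambda*||b||^2: both give b = (X'X + n lambda I)^{-1} X'y
  gx <- gaussianFixture(18, 5, seed = 97)
  lam <- 0.6
  f <- fitPath(gx$X, gx$y, lam, alpha = 0)
  n <- nrow(gx$X)
  Xc <- sweep(gx$X, 2, colMeans(gx$X)); yc <- gx$y - mean(gx$y)
  bPRSS <- solve(crossprod(Xc) + n * lam * diag(5), crossprod(Xc, yc))
  expect_equal(unname(coef(f)[, 1]), as.numeric(bPRSS), tolerance = 1e-10)
})

test_that("predictions follow the explicit linear form", {
  gx <- gaussianFixture(20, 6, seed = 101)
  f <- fitPath(gx$X, gx$y, c(1, 0.2), alpha = 0)
  Xnew <- matrix(rnorm(18), 3, 6)
  got <- predict(f, Xnew, lambdaIndex = 2L)
  # direct-summation oracle
  want <- numeric(3)
  for (i in 1:3) {
    s <- f@intercepts[2]
    for (j in 1:6) s <- s + Xnew[i, j] * coef(f)[j, 2]
    want[i] <- s
  }
  expect_equal(got, want)
  expect_error(predict(f, Xnew, lambdaIndex = 3L), "out of range")

  # zero coefficients predict the intercept everywhere
  fbig <- fitPath(gx$X, gx$y, 1e9, alpha = 0)
  expect_equal(predict(fbig, Xnew, lambdaIndex = 1L),
               rep(fbig@intercepts[1], 3), tolerance = 1e-6)

  # OLS limit: single-lambda refit at lambda ~ 0 with n > p reproduces
  # the least-squares fitted values on the training rows
  pred <- predict(f, gx$X, lambdaIndex = NULL)
  f00 <- fitPath(gx$X, gx$y, 1e-12, alpha = 0)
  expect_equal(predict(f00, gx$X, lambdaIndex = 1L),
               unname(lm.fit(cbind(1, gx$X), gx$y)$fitted.values),
               tolerance = 1e-6)
  expect_identical(dim(pred), c(20L, 2L))
})

test_that("independent lasso implementation agrees with coordinate descent", {
  skip_if_not_installed("glmnet")
  gx <- gaussianFixture(40, 25, seed = 103)
  lam <- c(0.8, 0.3, 0.1)
  f <- fitPath(gx$X, gx$y, lam, alpha = 1, tol = 1e-12)
  g <- glmnet::glmnet(gx$X, gx$y, alpha = 1, lambda = lam,
                      standardize = FALSE, thresh = 1e-14)
  expect_equal(unname(as.matrix(g$beta)), unname(coef(f)),
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("invalid solver inputs are rejected", {
  gx <- gaussianFixture(10, 3, seed = 107)
  expect_error(fitPath(gx$X, gx$y, 1, alpha = 2), "alpha")
  expect_error(fitPath(gx$X, gx$y, -1), "nonnegative")
  Xbad <- gx$X; Xbad[1, 1] <- NA
  expect_error(fitPath(Xbad, gx$y, 1), "non-finite")
  expect_error(fitPath(gx$X, gx$y, 1, engine = "exact", alpha = 0.5),
               "only available for ridge")
})
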