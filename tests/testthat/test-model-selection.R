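test_that("fold partitions are balanced, exhaustive and seeded", {
  f1 <- makeFolds(20, 10, seed = 1)
  expect_identical(sort(unique(f1)), 1:10)
  expect_true(all(table(f1) == 2L))

  f2 <- makeFolds(23, 10, seed = 2)
  expect_identical(as.integer(sort(table(f2))), c(rep(2L, 7), rep(3L, 3)))

  expect_identical(makeFolds(57, 10, seed = 9), makeFolds(57, 10, seed = 9))
  expect_false(identical(makeFolds(57, 10, seed = 9),
                         makeFolds(57, 10, seed = 10)))
  expect_error(makeFolds(5, 10), "at least")
  # fold construction does not disturb the caller's RNG stream
  set.seed(123); a <- rnorm(1)
  set.seed(123); invisible(makeFolds(30, 5, seed = 77)); b <- rnorm(1)
  expect_identical(a, b)
})

test_that("leave-one-out tuning matches a brute-force refit loop", {
  X <- simulateGenotypes(12, 8, seed = 201)
  ph <- simulatePhenotype(X, 4, 0.6, seed = 202)
  y <- ph$y
  cv <- innerCV(X, y, "variance_ratio", k = 12, seed = 5, nPoints = 20)
  grid <- lambdaValues(cv)

  # brute force: refit n times with explicit loops, same shared grid
  perSample <- matrix(NA_real_, 12, length(grid))
  for (i in 1:12) {
    st <- suppressWarnings(fitStandardizer(X[-i, , drop = FALSE], y[-i]))
    trn <- applyStandardizer(X[-i, , drop = FALSE], st, y[-i])
    val <- applyStandardizer(X[i, , drop = FALSE], st)
    fit <- fitPath(trn$Xs, trn$ys, grid, alpha = 0)
    pred <- st@responseMean + st@responseSd * predict(fit, val$Xs)
    perSample[i, ] <- (y[i] - pred)^2
  }
  expect_equal(cv@meanMse, unname(colMeans(perSample)), tolerance = 1e-10)
})

test_that("pure noise tunes to heavy shrinkage, pure signal to light", {
  topHalf <- 0L
  bottomDecile <- 0L
  for (s in 1:10) {
    X <- simulateGenotypes(100, 40, seed = 300 + s)
    yNoise <- withr::with_seed(400 + s, rnorm(100))
    cv <- innerCV(X, yNoise, "conventional", k = 10, seed = s)
    if (cv@lambdaOptIndex <= 50L) topHalf <- topHalf + 1L

    Xn <- simulateGenotypes(60, 10, seed = 500 + s)
    phn <- simulatePhenotype(Xn, 10, 0.95, seed = 600 + s)
    # near-noiseless: y = mu + g with tiny residual share
    cv2 <- innerCV(Xn, phn$y, "conventional", k = 10, seed = s)
    if (cv2@lambdaOptIndex > 90L) bottomDecile <- bottomDecile + 1L
  }
  expect_gte(topHalf, 8L)
  expect_gte(bottomDecile, 8L)
})

test_that("the shared grid comes from the outer-training set and folds stay sealed", {
  X <- simulateGenotypes(40, 100, seed = 211)
  ph <- simulatePhenotype(X, 20, 0.5, seed = 212)
  cv <- suppressWarnings(innerCV(X, ph$y, "conventional", k = 5, seed = 3))
  # grid equals the one built from the full standardized training set
  st <- suppressWarnings(fitStandardizer(X, ph$y))
  sdat <- applyStandardizer(X, st, ph$y)
  expect_identical(lambdaValues(cv),
                   lambdaValues(conventionalGrid(sdat$Xs, sdat$ys)))

  # every fold's losses are reproducible from the inner-training block
  # alone plus the shared grid: validation rows enter only as evaluation
  # points, never the standardization or the fit
  grid <- cv@grid
  for (f in 1:5) {
    idxVal <- which(cv@foldAssignment == f)
    idxTrn <- which(cv@foldAssignment != f)
    stF <- suppressWarnings(fitStandardizer(X[idxTrn, , drop = FALSE],
                                            ph$y[idxTrn]))
    trn <- applyStandardizer(X[idxTrn, , drop = FALSE], stF, ph$y[idxTrn])
    val <- applyStandardizer(X[idxVal, , drop = FALSE], stF)
    fit <- fitPath(trn$Xs, trn$ys, grid, alpha = 0)
    pred <- stF@responseMean + stF@responseSd * predict(fit, val$Xs)
    expect_equal(cv@foldMse[f, ],
                 unname(colMeans((ph$y[idxVal] - pred)^2)),
                 tolerance = 1e-12)
  }
})

test_that("tuning is deterministic and ties favor the larger lambda", {
  X <- simulateGenotypes(36, 60, seed = 221)
  ph <- simulatePhenotype(X, 12, 0.4, seed = 222)
  cv1 <- innerCV(X, ph$y, "variance_ratio", seed = 11)
  cv2 <- innerCV(X, ph$y, "variance_ratio", seed = 11)
  expect_identical(cv1@lambdaOpt, cv2@lambdaOpt)
  expect_identical(cv1@foldMse, cv2@foldMse)
  expect_identical(cvResultToJSON(cv1), cvResultToJSON(cv2))
  # the selected index is the first (largest-lambda) minimizer
  expect_identical(cv1@lambdaOptIndex,
                   as.integer(which.min(cv1@meanMse)))
  expect_identical(cv1@lambdaOpt, lambdaValues(cv1)[cv1@lambdaOptIndex])
  # fold losses are recorded both as sums and per-observation means
  sizes <- as.integer(table(cv1@foldAssignment))
  expect_equal(cv1@foldSse, cv1@foldMse * sizes)
})

test_that("refit on the full training set matches the closed-form oracle", {
  X <- simulateGenotypes(30, 45, seed = 231)
  ph <- simulatePhenotype(X, 9, 0.5, seed = 232)
  cv <- innerCV(X, ph$y, "variance_ratio", k = 5, seed = 7)
  m1 <- refitFull(X, ph$y, lambdaOpt(cv))
  m2 <- refitFull(X, ph$y, lambdaOpt(cv))
  expect_equal(coef(m1@fit), coef(m2@fit))

  st <- fitStandardizer(X, ph$y)
  sdat <- applyStandardizer(X, st, ph$y)
  expect_equal(unname(coef(m1@fit)[, 1]),
               ridgeOracle(sdat$Xs, sdat$ys, lambdaOpt(cv)),
               tolerance = 1e-8)

  # total shrinkage: predictions collapse to the training mean
  mBig <- refitFull(X, ph$y, 1e9)
  Xnew <- simulateGenotypes(5, 45, seed = 233)
  expect_equal(unname(predict(mBig, Xnew)), rep(mean(ph$y), 5),
               tolerance = 1e-5)
})
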