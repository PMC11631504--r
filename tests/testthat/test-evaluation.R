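test_that("Pearson correlation and NRMSE follow their definitions", {
  y <- c(1, 2, 3, 4)
  expect_equal(pearsonCor(y, 2 * y + 1), 1)
  expect_equal(pearsonCor(y, -y), -1)
  # hand computation of the sum formulas for (1,2,3,4) vs (2,1,4,3)
  yp <- c(2, 1, 4, 3)
  num <- sum((y - mean(y)) * (yp - mean(yp)))
  den <- sqrt(sum((y - mean(y))^2) * sum((yp - mean(yp))^2))
  expect_equal(num / den, 0.6)
  expect_equal(pearsonCor(y, yp), 0.6)
  expect_warning(r <- pearsonCor(c(1, 1, 1), y[1:3]), "constant")
  expect_true(is.na(r))
  expect_error(pearsonCor(1:2, 1:2), "at least 3")

  expect_equal(nrmse(y, y), 0)
  expect_equal(nrmse(c(2, 2, 2, 2), c(3, 3, 3, 3)), 0.5)
  # scale invariance of rmse/mean
  yhat <- yp + 0.3
  expect_equal(nrmse(3.7 * y, 3.7 * yhat), nrmse(y, yhat))
  expect_error(nrmse(c(-1, 1), c(0, 0)), "zero-mean")
  expect_equal(nrmse(c(2, 2), c(3, 3), variant = "mse_over_mean"), 0.5)
  expect_equal(nrmse(c(2, 2), c(4, 4), variant = "mse_over_mean"), 2)
})

test_that("outer folds partition the data and runs are reproducible", {
  X <- simulateGenotypes(50, 120, seed = 401)
  ph <- simulatePhenotype(X, 30, 0.4, seed = 402)
  r1 <- outerEvaluate(X, ph$y, methods = c("conventional", "variance_ratio"),
                      kOuter = 5, kInner = 5, seed = 17, nPoints = 40)
  # union of outer test blocks is the full index set, pairwise disjoint
  expect_identical(sort(unique(r1@foldAssignment)), 1:5)
  expect_identical(length(r1@foldAssignment), 50L)

  r2 <- outerEvaluate(X, ph$y, methods = c("conventional", "variance_ratio"),
                      kOuter = 5, kInner = 5, seed = 17, nPoints = 40)
  expect_identical(perFoldMetrics(r1), perFoldMetrics(r2))

  # duplicate method entries give identical metric columns (shared folds
  # and shared inner seeds)
  r3 <- outerEvaluate(X, ph$y, methods = c("conventional", "conventional"),
                      kOuter = 5, kInner = 5, seed = 17, nPoints = 40)
  pf <- perFoldMetrics(r3)
  half <- nrow(pf) / 2
  odd <- seq(1, nrow(pf), by = 2)
  expect_equal(pf$cor[odd], pf$cor[odd + 1])
  expect_equal(pf$lambdaOpt[odd], pf$lambdaOpt[odd + 1])
})

test_that("a heritability-zero trait evaluates to chance-level accuracy", {
  cors <- c()
  for (s in 1:3) {
    X <- simulateGenotypes(60, 150, seed = 410 + s)
    ph <- simulatePhenotype(X, 30, 0, seed = 420 + s)
    r <- outerEvaluate(X, ph$y, methods = "variance_ratio", kOuter = 5,
                       kInner = 5, seed = s, nPoints = 40)
    cors <- c(cors, perFoldMetrics(r)$cor)
  }
  se <- sd(cors) / sqrt(length(cors))
  expect_lt(abs(mean(cors)), 2 * se + 0.05)
})

test_that("variance-ratio tuning stays competitive in the p >> n regime", {
  # the wider grid must not cost accuracy where the conventional path
  # already brackets the optimum; checked on the medium benchmark regime
  for (s in 1:2) {
    sc <- makeBenchmarkSuite(seed = s)$medium
    r <- outerEvaluate(sc$X, sc$y,
                       methods = c("conventional", "variance_ratio"),
                       kOuter = 10, kInner = 10, seed = s)
    pf <- perFoldMetrics(r)
    mConv <- mean(pf$cor[pf$method == "conventional"], na.rm = TRUE)
    mVr <- mean(pf$cor[pf$method == "variance_ratio"], na.rm = TRUE)
    expect_gte(mVr, mConv - 0.02)
    lr <- lambdaRatioDiagnostic(r)
    expect_identical(lr$nFolds, 10L)
    expect_true(all(is.finite(lr$logRatio)))
  }
})

test_that("lambda-ratio diagnostic computes per-fold log ratios", {
  pf <- data.frame(
    method = rep(c("conventional", "variance_ratio"), each = 3),
    trait = "t", fold = rep(1:3, 2),
    cor = 0.5, nrmse = 0.1,
    lambdaOpt = c(10, 10, 50, 10, 1, 5))
  rep1 <- new("EvaluationReport", perFold = pf, trait = "t",
              foldAssignment = rep(1:3, 4),
              methods = c("conventional", "variance_ratio"),
              seed = 1L, alpha = 0)
  d <- lambdaRatioDiagnostic(rep1)
  expect_equal(d$logRatio, c(0, log(10), log(10)))
  expect_identical(d$nPositive, 2L)
  rep2 <- new("EvaluationReport",
              perFold = pf[pf$method == "conventional", ], trait = "t",
              foldAssignment = rep(1:3, 2), methods = "conventional",
              seed = 1L, alpha = 0)
  expect_error(lambdaRatioDiagnostic(rep2), "both grid methods")
})

makeToyReport <- function(trait, cors, lambdas = NULL) {
  methods <- c("conventional", "variance_ratio")
  pf <- do.call(rbind, lapply(seq_along(methods), function(i) {
    data.frame(method = methods[i], trait = trait,
               fold = seq_along(cors[[i]]), cor = cors[[i]],
               nrmse = 0.2 + 0.01 * i,
               lambdaOpt = if (is.null(lambdas)) 1 else lambdas[[i]])
  }))
  new("EvaluationReport", perFold = pf, trait = trait,
      foldAssignment = rep(1L, 3), methods = methods, seed = 1L,
      alpha = 0)
}

test_that("aggregation reproduces fold means, SDs and percent gains", {
  r <- makeToyReport("t1", list(c(0.1, 0.2, 0.3), c(0.2, 0.3, 0.4)))
  agg <- aggregateReports(list(ds = list(r)))
  pt <- agg$perTrait
  conv <- pt[pt$method == "conventional", ]
  expect_equal(conv$corMean, 0.2)
  expect_equal(conv$corSD, 0.1)  # sample SD convention
  vr <- pt[pt$method == "variance_ratio", ]
  expect_equal(vr$pctGainCor, 100 * (0.3 - 0.2) / 0.2)

  # single-trait dataset: SD across traits is 0
  expect_true(all(agg$perDataset$corSD == 0))
  expect_true(all(agg$perDataset$nrmseSD == 0))

  # two identical datasets: across-dataset SD is 0
  agg2 <- aggregateReports(list(d1 = list(r), d2 = list(r)))
  expect_true(all(agg2$acrossDatasets$corSD == 0))
  expect_identical(agg2$acrossDatasets$nDatasets, c(2L, 2L))

  # per-trait means equal the arithmetic mean of per-fold values
  expect_equal(conv$corMean,
               mean(perFoldMetrics(r)$cor[perFoldMetrics(r)$method ==
                                            "conventional"]))

  bad <- new("EvaluationReport",
             perFold = perFoldMetrics(r)[perFoldMetrics(r)$method ==
                                           "conventional", ],
             trait = "t2", foldAssignment = rep(1L, 3),
             methods = "conventional", seed = 1L, alpha = 0)
  expect_error(aggregateReports(list(d1 = list(r), d2 = list(bad))),
               "same method set")
})

test_that("per-fold reports serialize to tidy CSV deterministically", {
  X <- simulateGenotypes(40, 80, seed = 451)
  ph <- simulatePhenotype(X, 20, 0.5, seed = 452)
  r <- outerEvaluate(X, ph$y, methods = "variance_ratio", kOuter = 4,
                     kInner = 4, seed = 2, nPoints = 30)
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  writeReport(r, p1)
  writeReport(r, p2)
  expect_identical(readLines(p1), readLines(p2))
  df <- read.csv(p1)
  expect_identical(names(df),
                   c("method", "trait", "fold", "cor", "nrmse", "lambdaOpt"))
  expect_identical(nrow(df), 4L)
})
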