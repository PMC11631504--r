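#' Random k-fold partition
#'
#' Partitions `n` samples into `k` folds of sizes differing by at most one,
#' by random assignment under the given seed. Deterministic given the seed;
#' the caller's RNG state is left untouched.
#'
#' @param n sample count.
#' @param k fold count (default 10).
#' @param seed integer RNG seed.
#' @return integer vector of fold labels in `1:k`, length `n`.
#' @export
makeFolds <- function(n, k = 10L, seed = 1L) {
  n <- as.integer(n)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("n must be at least k")
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  withSeed(seed, sample(rep.int(seq_len(k), sizes)))
}

#' Inner cross-validation over a lambda grid
#'
#' Tunes the penalty on an (outer-)training set by k-fold cross-validation.
#' The candidate grid is built once from the full training set
#' (standardized with [fitStandardizer()]) and shared across the inner
#' folds, matching `cv.glmnet`'s behavior. Within each inner fold the
#' standardization is refit on the inner-training block only (no leakage
#' into fold-level fitting), the path is fitted, validation predictions are
#' back-transformed, and squared errors are accumulated per lambda on the
#' original response scale — both as raw sums and as per-observation means.
#' The selected lambda minimizes the across-fold mean of the
#' per-observation errors; exact ties go to the largest lambda (the more
#' regularized model).
#'
#' @param X genotype matrix of the outer-training set, original scale.
#' @param y response vector, original scale.
#' @param gridMethod `"conventional"` or `"variance_ratio"`.
#' @param alpha mixing parameter (default 0, ridge).
#' @param k inner fold count (default 10).
#' @param seed integer seed for the inner fold partition.
#' @param nPoints grid length (default 100).
#' @param grid optional pre-built [LambdaGrid-class] overriding
#'   `gridMethod`/`nPoints`.
#' @return a [CVResult-class].
#' @export
innerCV <- function(X, y, gridMethod = c("conventional", "variance_ratio"),
                    alpha = 0, k = 10L, seed = 1L, nPoints = 100L,
                    grid = NULL) {
  X <- asMatrix(X)
  y <- asNumericVector(y)
  n <- nrow(X)
  k <- as.integer(k)
  if (n < k) stop("need at least k samples for k-fold tuning")

  statsFull <- fitStandardizer(X, y)
  sdFull <- applyStandardizer(X, statsFull, y)
  if (is.null(grid)) {
    gridMethod <- match.arg(gridMethod)
    grid <- switch(gridMethod,
      conventional = conventionalGrid(sdFull$Xs, sdFull$ys, nPoints),
      variance_ratio = varianceRatioGrid(sdFull$Xs,
                                         sY2 = statsFull@responseSd^2,
                                         nPoints = nPoints))
  }
  stopifnot(is(grid, "LambdaGrid"))
  L <- length(grid@values)

  folds <- makeFolds(n, k, seed)
  foldSse <- matrix(NA_real_, k, L)
  foldMse <- matrix(NA_real_, k, L)
  for (f in seq_len(k)) {
    idxVal <- which(folds == f)
    idxTrn <- which(folds != f)
    statsF <- suppressWarnings(fitStandardizer(X[idxTrn, , drop = FALSE],
                                               y[idxTrn]))
    trn <- applyStandardizer(X[idxTrn, , drop = FALSE], statsF, y[idxTrn])
    val <- applyStandardizer(X[idxVal, , drop = FALSE], statsF)
    fit <- fitPath(trn$Xs, trn$ys, grid, alpha = alpha)
    predStd <- predict(fit, val$Xs)               # n_val x L
    pred <- statsF@responseMean + statsF@responseSd * predStd
    err2 <- (y[idxVal] - pred)^2
    foldSse[f, ] <- colSums(err2)
    foldMse[f, ] <- colMeans(err2)
  }
  meanMse <- colMeans(foldMse)
  # grid is descending, so the first minimizer is the largest lambda
  iOpt <- which.min(meanMse)

  new("CVResult",
      grid = grid,
      foldMse = foldMse,
      foldSse = foldSse,
      meanMse = meanMse,
      lambdaOpt = grid@values[iOpt],
      lambdaOptIndex = as.integer(iOpt),
      foldAssignment = as.integer(folds),
      seed = as.integer(seed),
      alpha = alpha)
}

#' Refit the tuned model on the full training set
#'
#' Refits the standardization and the penalized model on the complete
#' (outer-)training set at a single selected lambda, returning the fit
#' bundled with its standardization statistics so held-out predictions can
#' be produced on the observed scale.
#'
#' @param X training genotype matrix, original scale.
#' @param y training response, original scale.
#' @param lambdaOpt the tuned penalty (from [innerCV()]).
#' @param alpha mixing parameter (default 0).
#' @return a [SelectedModel-class].
#' @export
refitFull <- function(X, y, lambdaOpt, alpha = 0) {
  if (!is.numeric(lambdaOpt) || length(lambdaOpt) != 1L || lambdaOpt < 0)
    stop("lambdaOpt must be a single nonnegative value")
  stats <- fitStandardizer(X, y)
  sdat <- applyStandardizer(X, stats, y)
  fit <- fitPath(sdat$Xs, sdat$ys, lambdaOpt, alpha = alpha)
  new("SelectedModel", fit = fit, stats = stats,
      lambda = lambdaOpt, alpha = alpha)
}

#' Predict phenotypes from a tuned model
#'
#' Standardizes new genotypes with the model's training statistics,
#' applies the penalized fit, and back-transforms to the observed
#' phenotype scale.
#'
#' @param object a [SelectedModel-class].
#' @param newdata genotype matrix on the original scale.
#' @return numeric vector of predictions on the observed phenotype scale.
#' @export
setMethod("predict", "SelectedModel", function(object, newdata) {
  Xs <- applyStandardizer(newdata, object@stats)$Xs
  invertPredictions(predict(object@fit, Xs, lambdaIndex = 1L), object@stats)
})

#' Serialize an inner-CV result to JSON
#'
#' Captures the grid (values and provenance), per-fold losses, selection
#' and seed in a reproducible JSON document.
#'
#' @param cv a [CVResult-class].
#' @param path output path; when `NULL` the JSON string is returned.
#' @return the path (invisibly) or a JSON string.
#' @export
cvResultToJSON <- function(cv, path = NULL) {
  stopifnot(is(cv, "CVResult"))
  obj <- list(
    grid = list(method = cv@grid@method, values = cv@grid@values,
                provenance = cv@grid@provenance),
    foldMse = cv@foldMse,
    foldSse = cv@foldSse,
    meanMse = cv@meanMse,
    lambdaOpt = cv@lambdaOpt,
    lambdaOptIndex = cv@lambdaOptIndex,
    foldAssignment = cv@foldAssignment,
    seed = cv@seed,
    alpha = cv@alpha
  )
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
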