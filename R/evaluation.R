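#' Pearson correlation between observed and predicted values
#'
#' Standard product-moment correlation; when either vector is constant the
#' correlation is undefined and `NA` is returned with a warning (such
#' folds are excluded from averages, with the exclusion counted).
#'
#' @param yObs observed values.
#' @param yPred predicted values.
#' @return numeric(1) in `[-1, 1]`, or `NA`.
#' @export
pearsonCor <- function(yObs, yPred) {
  yObs <- asNumericVector(yObs, "yObs")
  yPred <- asNumericVector(yPred, "yPred")
  if (length(yObs) != length(yPred)) stop("length mismatch")
  if (length(yObs) < 3L) stop("at least 3 observations are required")
  if (stats::sd(yObs) == 0 || stats::sd(yPred) == 0) {
    warning("correlation undefined for a constant vector; returning NA")
    return(NA_real_)
  }
  stats::cor(yObs, yPred)
}

#' Normalized root mean squared error
#'
#' \eqn{NRMSE = \sqrt{MSE} / \bar y_{obs}} with
#' \eqn{MSE = (1/n)\sum_i (y_i - \hat y_i)^2}: the root mean squared error
#' normalized by the mean of the observed test values, so the metric is
#' comparable across traits of different scales. The `variant`
#' `"mse_over_mean"` divides the (un-rooted) MSE by the observed mean
#' instead; it is exposed because the two readings differ only by the root
#' and real-data reproductions may need either.
#'
#' @param yObs observed values (mean must be nonzero).
#' @param yPred predicted values.
#' @param variant `"rmse_over_mean"` (default) or `"mse_over_mean"`.
#' @return nonnegative numeric(1).
#' @export
nrmse <- function(yObs, yPred, variant = c("rmse_over_mean",
                                           "mse_over_mean")) {
  variant <- match.arg(variant)
  yObs <- asNumericVector(yObs, "yObs")
  yPred <- asNumericVector(yPred, "yPred")
  if (length(yObs) != length(yPred)) stop("length mismatch")
  m <- mean(yObs)
  if (m == 0) stop("NRMSE undefined for zero-mean response")
  mse <- mean((yObs - yPred)^2)
  switch(variant,
         rmse_over_mean = sqrt(mse) / m,
         mse_over_mean = mse / m)
}

#' Outer cross-validation benchmark of tuning methods
#'
#' Runs the nested evaluation protocol: the data are split into `kOuter`
#' outer folds (identical for every compared method); within each outer
#' training set the penalty is tuned by [innerCV()] with `kInner` folds
#' (identical inner seeds across methods, making comparisons paired), the
#' tuned model is refitted on the full outer-training set, and the
#' held-out fold is predicted. Pearson correlation and NRMSE are computed
#' per fold on the observed phenotype scale. The GBLUP comparator is fit
#' on the same outer folds with allele frequencies estimated from the
#' training partition.
#'
#' @param X dosage matrix, lines x markers.
#' @param y response vector.
#' @param methods subset of `c("conventional", "variance_ratio", "gblup")`.
#' @param alpha mixing parameter for the grid methods (default 0).
#' @param kOuter,kInner outer/inner fold counts (default 10 each).
#' @param seed top-level integer seed; outer folds and all inner seeds
#'   derive from it deterministically.
#' @param nPoints grid length (default 100).
#' @param trait trait label carried into the report.
#' @param nrmseVariant passed to [nrmse()].
#' @param gFreqMode `"training"` (default) estimates allele frequencies
#'   for the G matrix from each outer-training partition; `"all"` uses all
#'   lines once.
#' @return an [EvaluationReport-class].
#' @export
outerEvaluate <- function(X, y,
                          methods = c("conventional", "variance_ratio"),
                          alpha = 0, kOuter = 10L, kInner = 10L,
                          seed = 1L, nPoints = 100L, trait = "trait",
                          nrmseVariant = "rmse_over_mean",
                          gFreqMode = c("training", "all")) {
  X <- asMatrix(X)
  y <- asNumericVector(y)
  n <- nrow(X)
  methods <- match.arg(methods,
                       c("conventional", "variance_ratio", "gblup"),
                       several.ok = TRUE)
  gFreqMode <- match.arg(gFreqMode)
  folds <- makeFolds(n, kOuter, seed)
  ids <- rownames(X)
  if (is.null(ids)) {
    ids <- paste0("line", seq_len(n))
    rownames(X) <- ids
  }

  rows <- list()
  for (f in seq_len(kOuter)) {
    idxTst <- which(folds == f)
    idxTrn <- which(folds != f)
    innerSeed <- deriveSeed(seed, f)
    yTst <- y[idxTst]
    corOK <- stats::sd(yTst) > 0
    if (!corOK)
      warning(sprintf("constant test response in outer fold %d; metrics set to NA", f))

    for (meth in methods) {
      if (meth %in% c("conventional", "variance_ratio")) {
        cv <- innerCV(X[idxTrn, , drop = FALSE], y[idxTrn],
                      gridMethod = meth, alpha = alpha, k = kInner,
                      seed = innerSeed, nPoints = nPoints)
        model <- refitFull(X[idxTrn, , drop = FALSE], y[idxTrn],
                           cv@lambdaOpt, alpha = alpha)
        pred <- predict(model, X[idxTst, , drop = FALSE])
        lam <- cv@lambdaOpt
      } else {
        freqRows <- if (gFreqMode == "training") idxTrn else NULL
        G <- vanRadenG(X, freqRows = freqRows)
        yMask <- y
        yMask[idxTst] <- NA_real_
        gf <- remlFit(yMask, G)
        pred <- unname(gblupPredict(gf, ids[idxTst]))
        lam <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        method = meth, trait = trait, fold = f,
        cor = if (corOK) suppressWarnings(pearsonCor(yTst, pred)) else NA_real_,
        nrmse = nrmse(yTst, pred, nrmseVariant),
        lambdaOpt = lam,
        stringsAsFactors = FALSE)
    }
  }

  new("EvaluationReport",
      perFold = do.call(rbind, rows),
      trait = trait,
      foldAssignment = as.integer(folds),
      methods = methods,
      seed = as.integer(seed),
      alpha = alpha)
}

#' Per-fold log-ratio of tuned penalties
#'
#' The diagnostic \eqn{\log(\lambda^{opt}_{conventional} /
#' \lambda^{opt}_{variance\_ratio})} per outer fold, with a count of
#' positive ratios. Positive values mean the conventional path selected a
#' stronger penalty than the variance-ratio grid on the same fold.
#'
#' @param report an [EvaluationReport-class] containing both grid methods.
#' @return list with `logRatio` (per fold), `nPositive`, `nFolds`.
#' @export
lambdaRatioDiagnostic <- function(report) {
  stopifnot(is(report, "EvaluationReport"))
  pf <- report@perFold
  if (!all(c("conventional", "variance_ratio") %in% pf$method))
    stop("report must contain both grid methods")
  conv <- pf[pf$method == "conventional", ]
  vr <- pf[pf$method == "variance_ratio", ]
  conv <- conv[order(conv$fold), ]
  vr <- vr[order(vr$fold), ]
  lr <- log(conv$lambdaOpt / vr$lambdaOpt)
  list(logRatio = lr, nPositive = sum(lr > 0), nFolds = length(lr))
}

#' Aggregate evaluation reports across traits and datasets
#'
#' Builds the standard summary tables from per-trait reports:
#' `perTrait` (per trait and method: mean and sample SD of each metric
#' across folds), `perDataset` (per dataset and method: mean and sample SD
#' across traits of the fold-means; SD is 0 for single-trait datasets) and
#' `acrossDatasets` (mean and sample SD of the per-dataset means). A
#' percent-gain column \eqn{100(\mathrm{Cor}_{vr} -
#' \mathrm{Cor}_{conv})/\mathrm{Cor}_{conv}} is attached per trait and per
#' dataset when both grid methods are present. Folds with undefined
#' correlation are excluded from averages and counted in `nMissingCor`.
#'
#' @param reports a list of [EvaluationReport-class] objects, or a named
#'   list of such lists (one element per dataset).
#' @return list of data.frames `perTrait`, `perDataset`,
#'   `acrossDatasets`.
#' @export
aggregateReports <- function(reports) {
  if (is(reports, "EvaluationReport")) reports <- list(reports)
  if (all(vapply(reports, is, logical(1), "EvaluationReport")))
    reports <- list(dataset1 = reports)
  methodSets <- unique(lapply(reports, function(ds)
    sort(unique(unlist(lapply(ds, function(r) r@methods))))))
  if (length(methodSets) != 1L)
    stop("all reports must share the same method set")

  perTrait <- do.call(rbind, lapply(names(reports), function(ds) {
    do.call(rbind, lapply(reports[[ds]], function(r) {
      pf <- r@perFold
      do.call(rbind, lapply(split(pf, pf$method), function(g) {
        data.frame(dataset = ds, trait = r@trait, method = g$method[1L],
                   corMean = mean(g$cor, na.rm = TRUE),
                   corSD = stats::sd(g$cor[!is.na(g$cor)]),
                   nrmseMean = mean(g$nrmse, na.rm = TRUE),
                   nrmseSD = stats::sd(g$nrmse[!is.na(g$nrmse)]),
                   nFolds = nrow(g),
                   nMissingCor = sum(is.na(g$cor)),
                   stringsAsFactors = FALSE)
      }))
    }))
  }))
  rownames(perTrait) <- NULL
  perTrait <- attachGain(perTrait, c("dataset", "trait"))

  perDataset <- do.call(rbind, lapply(split(perTrait, perTrait$dataset),
                                      function(d) {
    do.call(rbind, lapply(split(d, d$method), function(g) {
      data.frame(dataset = d$dataset[1L], method = g$method[1L],
                 corMean = mean(g$corMean),
                 corSD = if (nrow(g) > 1L) stats::sd(g$corMean) else 0,
                 nrmseMean = mean(g$nrmseMean),
                 nrmseSD = if (nrow(g) > 1L) stats::sd(g$nrmseMean) else 0,
                 nTraits = nrow(g),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(perDataset) <- NULL
  perDataset <- attachGain(perDataset, "dataset")

  acrossDatasets <- do.call(rbind, lapply(split(perDataset,
                                                perDataset$method),
                                          function(g) {
    data.frame(method = g$method[1L],
               corMean = mean(g$corMean),
               corSD = if (nrow(g) > 1L) stats::sd(g$corMean) else 0,
               nrmseMean = mean(g$nrmseMean),
               nrmseSD = if (nrow(g) > 1L) stats::sd(g$nrmseMean) else 0,
               nDatasets = nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(acrossDatasets) <- NULL

  list(perTrait = perTrait, perDataset = perDataset,
       acrossDatasets = acrossDatasets)
}

# percent Cor gain of the variance-ratio grid over the conventional one,
# merged back onto a summary table keyed by `keys`
attachGain <- function(tab, keys) {
  if (!all(c("conventional", "variance_ratio") %in% tab$method)) {
    tab$pctGainCor <- NA_real_
    return(tab)
  }
  key <- do.call(paste, c(tab[keys], sep = "\r"))
  conv <- tab$method == "conventional"
  vr <- tab$method == "variance_ratio"
  gain <- 100 * (tab$corMean[vr][match(key, key[vr])] -
                   tab$corMean[conv][match(key, key[conv])]) /
    tab$corMean[conv][match(key, key[conv])]
  gain[!vr] <- NA_real_
  tab$pctGainCor <- gain
  tab
}

#' Write per-fold metrics as tidy CSV
#'
#' One row per method x trait x fold, at full double precision.
#'
#' @param report an [EvaluationReport-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeReport <- function(report, path) {
  stopifnot(is(report, "EvaluationReport"))
  pf <- report@perFold
  for (col in c("cor", "nrmse", "lambdaOpt"))
    pf[[col]] <- format(pf[[col]], digits = 17L)
  utils::write.csv(pf, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
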