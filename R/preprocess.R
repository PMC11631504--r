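#' Fit training-set standardization statistics
#'
#' Computes per-marker means and standard deviations and the response mean
#' and SD on a training block, using the population variance convention
#' (divisor \eqn{n_{trn}}, not \eqn{n_{trn}-1}) throughout. Marker columns
#' with zero variance in the training block are dropped with a warning and
#' recorded in the `dropped` slot, since cross-validation subsampling of
#' real marker data routinely produces monomorphic columns within a fold.
#'
#' @param X numeric matrix, training genotypes (lines x markers); no
#'   missing values.
#' @param y numeric vector, training response, `length(y) == nrow(X)`.
#' @return a [StandardizationStats-class] object.
#' @examples
#' X <- matrix(c(0, 2, 1, 1), 2, 2)
#' y <- c(1, 3)
#' fitStandardizer(X[, 1, drop = FALSE], y)
#' @export
fitStandardizer <- function(X, y) {
  X <- asMatrix(X)
  y <- asNumericVector(y)
  n <- nrow(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n < 2L) stop("at least 2 training samples are required")

  mu <- colMeans(X)
  # population variance: divisor n, not n - 1
  v <- colMeans(X^2) - mu^2
  v[v < 0] <- 0
  sdx <- sqrt(v)

  keep <- sdx > 0
  if (!any(keep)) stop("no informative markers")
  dropped <- which(!keep)
  if (length(dropped))
    warning(sprintf("dropping %d zero-variance marker column(s)",
                    length(dropped)))

  ybar <- mean(y)
  sy <- sqrt(mean((y - ybar)^2))
  if (sy <= 0) stop("zero phenotypic variance")

  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("m", seq_len(ncol(X)))

  new("StandardizationStats",
      columnMeans = unname(mu[keep]),
      columnSds = unname(sdx[keep]),
      responseMean = ybar,
      responseSd = sy,
      nTrain = as.integer(n),
      dropped = as.integer(dropped),
      markerNames = cn[keep])
}

#' Standardize genotypes (and optionally a response) with training statistics
#'
#' Applies \eqn{(x - \bar x_{trn}) / \sigma_{trn}} column-wise using
#' statistics fitted on a training block; columns dropped at fitting time
#' are removed. The response, when supplied, is standardized analogously
#' with the training response mean and SD. Held-out data must be
#' transformed with the training statistics, never its own.
#'
#' @param X numeric matrix with the same marker columns the standardizer
#'   was fitted on.
#' @param stats a [StandardizationStats-class].
#' @param y optional numeric response vector.
#' @return list with elements `Xs` (standardized matrix) and `ys`
#'   (standardized response, or `NULL`).
#' @export
applyStandardizer <- function(X, stats, y = NULL) {
  stopifnot(is(stats, "StandardizationStats"))
  X <- asMatrix(X)
  pFull <- length(stats@columnSds) + length(stats@dropped)
  if (ncol(X) != pFull)
    stop(sprintf("column mismatch: standardizer fitted on %d columns, got %d",
                 pFull, ncol(X)))
  if (length(stats@dropped)) X <- X[, -stats@dropped, drop = FALSE]
  Xs <- sweep(X, 2L, stats@columnMeans, "-")
  Xs <- sweep(Xs, 2L, stats@columnSds, "/")
  ys <- NULL
  if (!is.null(y)) {
    y <- asNumericVector(y)
    ys <- (y - stats@responseMean) / stats@responseSd
  }
  list(Xs = Xs, ys = ys)
}

#' Back-transform standardized predictions to the observed phenotype scale
#'
#' The inverse of the response standardization:
#' \eqn{\hat y = \bar y_{trn} + \sigma_{y,trn}\,\hat y_{std}}. Prediction
#' metrics (Pearson correlation, NRMSE) are computed on this scale.
#'
#' @param ysHat numeric vector of predictions on the standardized scale.
#' @param stats the training [StandardizationStats-class].
#' @return numeric vector on the original response scale.
#' @export
invertPredictions <- function(ysHat, stats) {
  stopifnot(is(stats, "StandardizationStats"))
  stats@responseMean + stats@responseSd * as.numeric(ysHat)
}
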