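#' Conventional glmnet-style lambda path
#'
#' Re-implements the conventional candidate-lambda construction used by
#' `cv.glmnet` for ridge regression, from standardized training data:
#' \enumerate{
#'   \item element-wise products of each standardized marker column with the
#'     standardized response are summed per column and scaled as
#'     \eqn{S_{XY,j} = 1000\,\sum_i X_{ij} y_i / n_{trn}};
#'   \item \eqn{\lambda_{max} = \max_j S_{XY,j}};
#'   \item \eqn{\lambda_{min.ratio} = 0.01} when \eqn{p > n_{trn}},
#'     else \eqn{10^{-4}};
#'   \item \eqn{\lambda_{min} = \lambda_{max}\,\lambda_{min.ratio}};
#'   \item `nPoints` values equally spaced between
#'     \eqn{\log\lambda_{max}} and \eqn{\log\lambda_{min}}.
#' }
#' The factor 1000 is glmnet's internal surrogate (mixing parameter floored
#' at 0.001) for the ridge \eqn{\lambda_{max}}, which would otherwise be
#' infinite; it is reproduced literally. Values are returned in descending
#' order (warm-start friendly, matching glmnet's path convention).
#'
#' @param Xs standardized training genotype matrix (see
#'   [applyStandardizer()]).
#' @param ys standardized training response.
#' @param nPoints integer, grid length (default 100).
#' @return a [LambdaGrid-class] with method `"conventional"`.
#' @export
conventionalGrid <- function(Xs, ys, nPoints = 100L) {
  Xs <- asMatrix(Xs, "Xs")
  ys <- asNumericVector(ys, "ys")
  n <- nrow(Xs)
  p <- ncol(Xs)
  if (length(ys) != n) stop("length(ys) must equal nrow(Xs)")
  nPoints <- as.integer(nPoints)
  if (nPoints < 2L) stop("nPoints must be >= 2")

  sxy <- as.numeric(crossprod(Xs, ys)) * 1000 / n
  lambdaMax <- max(sxy)
  if (!is.finite(lambdaMax) || lambdaMax <= 0)
    stop("degenerate path: max inner product nonpositive")
  ratio <- if (p > n) 0.01 else 1e-4
  lambdaMin <- lambdaMax * ratio
  values <- exp(seq(log(lambdaMax), log(lambdaMin), length.out = nPoints))

  new("LambdaGrid",
      values = values,
      method = "conventional",
      nPoints = nPoints,
      provenance = list(lambdaMax = lambdaMax, lambdaMin = lambdaMin,
                        lambdaMinRatio = ratio))
}

#' Log-spaced sequence of explained-variance proportions
#'
#' The ordered proportions \eqn{R^2_l} of phenotypic variance attributed to
#' genotypic effects that the variance-ratio grid explores:
#' \deqn{R^2_l = \exp\!\left(\log 10^{-5} +
#'   \frac{\log 0.9999 - \log 10^{-5}}{n_{points}-1}(l-1)\right),
#'   \quad l = 1, \dots, n_{points},}
#' strictly increasing from \eqn{10^{-5}} to \eqn{0.9999}.
#'
#' @param nPoints integer >= 2 (default 100).
#' @return numeric vector of length `nPoints`.
#' @export
r2Sequence <- function(nPoints = 100L) {
  nPoints <- as.integer(nPoints)
  if (is.na(nPoints) || nPoints < 2L) stop("nPoints must be >= 2")
  exp(seq(log(1e-5), log(0.9999), length.out = nPoints))
}

#' Variance-component-ratio lambda grid
#'
#' Builds the proposed candidate grid by equating each penalty to a ratio
#' of variance components. For a proportion \eqn{R^2_l} of phenotypic
#' variance \eqn{s_y^2} explained by genotypic effects, the error and
#' coefficient variances are \eqn{\sigma_l^2 = (1-R^2_l)s_y^2} and
#' \eqn{\sigma_{l\beta}^2 = R^2_l s_y^2 / m} with
#' \eqn{m = (1/n_{trn})\sum_i x_i^\top x_i} the mean squared row norm, so
#' \deqn{\lambda_l = \frac{\sigma_l^2}{\sigma_{l\beta}^2}
#'   = \frac{1-R^2_l}{R^2_l / m} = m\,\frac{1-R^2_l}{R^2_l}.}
#' \eqn{s_y^2} cancels; it is still accepted and its irrelevance is part of
#' the tested contract. After 1/n-standardization \eqn{m = p} exactly, so
#' \eqn{\lambda_l = p\,(1-R^2_l)/R^2_l}. The grid is returned descending
#' (largest lambda corresponds to the smallest \eqn{R^2_l}).
#'
#' @param Xs standardized training genotype matrix.
#' @param sY2 phenotypic variance of the training response (default 1, the
#'   standardized-scale value); cancels out of the grid.
#' @param nPoints integer, grid length (default 100).
#' @return a [LambdaGrid-class] with method `"variance_ratio"`.
#' @export
varianceRatioGrid <- function(Xs, sY2 = 1, nPoints = 100L) {
  Xs <- asMatrix(Xs, "Xs")
  if (!is.numeric(sY2) || length(sY2) != 1L || sY2 <= 0)
    stop("sY2 must be a single positive number")
  r2 <- r2Sequence(nPoints)
  m <- mean(rowSums(Xs^2))
  if (m <= 0) stop("mean squared row norm is zero")
  # sigma_l^2 / sigma_lbeta^2 = ((1-R2) sY2) / (R2 sY2 / m): the phenotypic
  # variance cancels exactly, so the cancelled form is evaluated
  values <- m * (1 - r2) / r2

  new("LambdaGrid",
      values = values,
      method = "variance_ratio",
      nPoints = as.integer(nPoints),
      provenance = list(r2 = r2, sY2 = sY2, m = m))
}

#' Export a lambda grid as a two-column CSV
#'
#' Writes `index,lambda` rows at full double precision for downstream
#' diagnostics (e.g. grid-support histograms).
#'
#' @param grid a [LambdaGrid-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeLambdaGrid <- function(grid, path) {
  stopifnot(is(grid, "LambdaGrid"))
  df <- data.frame(index = seq_along(grid@values),
                   lambda = format(grid@values, digits = 17L))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
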