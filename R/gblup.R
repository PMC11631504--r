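#' VanRaden genomic relationship matrix
#'
#' Computes \eqn{G = ZZ^\top / c} (VanRaden method 1) from a dosage matrix
#' coded in `[0, 2]`: allele frequencies \eqn{p_j} are half the column
#' means of the designated frequency rows, \eqn{Z = X - 2p} column-wise,
#' and \eqn{c = 2\sum_j p_j(1-p_j)}. Monomorphic markers (at the frequency
#' rows) contribute zero to \eqn{Z} and are excluded from the denominator.
#'
#' In cross-validation contexts frequencies should be estimated from the
#' training partition only (pass `freqRows`) to avoid using held-out
#' genotype information in the centering; computing them from all lines is
#' common practice and available by default.
#'
#' @param X dosage matrix, lines x markers, values in `[0, 2]`.
#' @param freqRows optional integer/logical/character index of the rows
#'   used to estimate allele frequencies (default: all rows).
#' @return a [GenomicRelationship-class] covering all rows of `X`.
#' @export
vanRadenG <- function(X, freqRows = NULL) {
  X <- asMatrix(X)
  if (ncol(X) < 2L) stop("at least 2 markers are required")
  if (min(X) < -1e-8 || max(X) > 2 + 1e-8)
    stop("dosages must lie in [0, 2]")
  ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("line", seq_len(nrow(X)))

  Xf <- if (is.null(freqRows)) X else X[freqRows, , drop = FALSE]
  pj <- colMeans(Xf) / 2
  poly <- pj > 0 & pj < 1
  if (!any(poly)) stop("all markers are monomorphic")

  Z <- sweep(X[, poly, drop = FALSE], 2L, 2 * pj[poly], "-")
  cst <- 2 * sum(pj[poly] * (1 - pj[poly]))
  G <- tcrossprod(Z) / cst
  G <- (G + t(G)) / 2
  dimnames(G) <- list(ids, ids)

  new("GenomicRelationship",
      matrix = G,
      alleleFreqs = unname(pj),
      scaleConstant = cst,
      polymorphic = unname(poly),
      ids = ids)
}

# Restricted log-likelihood profiled over sigmaG2 and mu, as a function of
# delta = sigmaE2/sigmaG2, on the spectral decomposition of the training
# block of G. Returns the criterion and the profiled estimates.
remlProfile <- function(logDelta, d, uy, ux) {
  delta <- exp(logDelta)
  w <- 1 / (d + delta)
  xwx <- sum(w * ux^2)
  mu <- sum(w * ux * uy) / xwx
  rss <- sum(w * (uy - ux * mu)^2)
  nq <- length(d) - 1L
  sigmaG2 <- rss / nq
  ll <- -0.5 * (nq * (log(sigmaG2) + 1) + sum(log(d + delta)) + log(xwx))
  list(logLik = ll, mu = mu, sigmaG2 = sigmaG2, delta = delta)
}

#' REML fit of the GBLUP mixed model
#'
#' Fits \eqn{y_i = \mu + g_i + \epsilon_i} with
#' \eqn{g \sim N(0, \sigma_g^2 G)} by spectral profile REML: the training
#' block of \eqn{G} is eigendecomposed once and the restricted
#' log-likelihood, profiled over \eqn{\mu} and \eqn{\sigma_g^2}, is
#' maximized over \eqn{\delta = \sigma^2/\sigma_g^2} by 1-D bounded search
#' on the log scale over \eqn{[10^{-9}, 10^9]}. A coarse grid scan checks
#' that the optimizer is bracketed (recorded in the `bracketed` slot, with
#' a warning otherwise). BLUPs for all lines — including unphenotyped ones
#' — are \eqn{\hat g = G_{\cdot,trn}(G_{trn,trn}+\delta I)^{-1}
#' (y_{trn} - \hat\mu)}.
#'
#' @param y numeric response over all lines of `G`, with `NA` marking
#'   unphenotyped lines to predict; if named, aligned to `G` by name.
#' @param G a [GenomicRelationship-class] (or square numeric matrix)
#'   covering phenotyped and unphenotyped lines.
#' @return a [GblupFit-class].
#' @export
remlFit <- function(y, G) {
  if (is(G, "GenomicRelationship")) {
    ids <- G@ids
    Gm <- G@matrix
  } else {
    Gm <- asMatrix(G, "G")
    if (nrow(Gm) != ncol(Gm)) stop("G must be square")
    ids <- rownames(Gm)
    if (is.null(ids)) ids <- paste0("line", seq_len(nrow(Gm)))
  }
  nAll <- nrow(Gm)
  if (!is.null(names(y))) {
    if (!all(ids %in% names(y))) stop("names(y) must cover all lines of G")
    y <- y[ids]
  } else if (length(y) != nAll) {
    stop("length(y) must equal nrow(G)")
  }
  train <- which(!is.na(y))
  nTrn <- length(train)
  if (nTrn < 3L) stop("at least 3 phenotyped lines are required")
  yT <- as.numeric(y[train])

  Gtt <- Gm[train, train, drop = FALSE]
  e <- eigen(Gtt, symmetric = TRUE)
  if (min(e$values) < -1e-8) {
    warning("G is not numerically PSD; stabilizing diagonal by 1e-6")
    Gtt <- Gtt + diag(1e-6, nTrn)
    Gm[train, train] <- Gtt
    e <- eigen(Gtt, symmetric = TRUE)
  }
  d <- pmax(e$values, 0)
  uy <- as.numeric(crossprod(e$vectors, yT))
  ux <- as.numeric(crossprod(e$vectors, rep(1, nTrn)))

  lo <- log(1e-9)
  hi <- log(1e9)
  opt <- stats::optimize(function(ld) remlProfile(ld, d, uy, ux)$logLik,
                         interval = c(lo, hi), maximum = TRUE,
                         tol = 1e-8)
  # unimodality/bracketing check: coarse scan should not beat the line
  # search at either boundary
  scan <- seq(lo, hi, length.out = 41L)
  scanLL <- vapply(scan, function(ld) remlProfile(ld, d, uy, ux)$logLik,
                   numeric(1))
  iBest <- which.max(scanLL)
  bracketed <- iBest > 1L && iBest < length(scan)
  if (!bracketed)
    warning("REML coarse scan peaks at the search boundary; estimate may be degenerate")
  best <- if (max(scanLL) > opt$objective) {
    remlProfile(scan[iBest], d, uy, ux)
  } else {
    remlProfile(opt$maximum, d, uy, ux)
  }

  alphaC <- e$vectors %*% ((uy - ux * best$mu) / (d + best$delta))
  gAll <- as.numeric(Gm[, train, drop = FALSE] %*% alphaC)
  names(gAll) <- ids

  new("GblupFit",
      mu = best$mu,
      sigmaG2 = best$sigmaG2,
      sigmaE2 = best$sigmaG2 * best$delta,
      delta = best$delta,
      h2 = 1 / (1 + best$delta),
      blups = gAll,
      trainIds = ids[train],
      logLik = best$logLik,
      bracketed = bracketed)
}

#' GBLUP predictions on the observed scale
#'
#' \eqn{\hat y = \hat\mu + \hat g} for the requested lines.
#'
#' @param fit a [GblupFit-class].
#' @param ids character line identifiers (or integer indices into the
#'   lines of the fitted relationship matrix).
#' @return named numeric vector of predictions.
#' @export
gblupPredict <- function(fit, ids) {
  stopifnot(is(fit, "GblupFit"))
  if (is.character(ids) && !all(ids %in% names(fit@blups)))
    stop("unknown line ID(s): ",
         paste(setdiff(ids, names(fit@blups)), collapse = ", "))
  fit@mu + fit@blups[ids]
}

#' Read/write a genomic relationship matrix as square CSV
#'
#' The CSV carries line IDs as both header row and first column.
#'
#' @param G a [GenomicRelationship-class] or square matrix (for writing).
#' @param path file path.
#' @return `writeGRM` returns the path invisibly; `readGRM` returns a
#'   square numeric matrix with line-ID dimnames.
#' @export
writeGRM <- function(G, path) {
  Gm <- if (is(G, "GenomicRelationship")) G@matrix else G
  df <- data.frame(id = rownames(Gm),
                   apply(Gm, 2L, function(x) format(x, digits = 17L)),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeGRM
#' @export
readGRM <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- as.character(df[[1L]])
  Gm <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(Gm) <- "double"
  if (nrow(Gm) != ncol(Gm)) stop("relationship matrix file is not square")
  dimnames(Gm) <- list(ids, ids)
  Gm
}
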