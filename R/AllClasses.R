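#' @import methods
NULL

#' Standardization statistics for a training set
#'
#' Per-marker means and standard deviations (population convention, divisor
#' \eqn{n_{trn}}) of a training genotype block, together with the training
#' response mean and SD. These statistics define the standardization map
#' applied to training and held-out data and the affine back-transformation
#' of predictions to the observed phenotype scale.
#'
#' @slot columnMeans numeric, per-marker training mean.
#' @slot columnSds numeric, per-marker training SD with divisor `nTrain`
#'   (not `nTrain - 1`); all strictly positive.
#' @slot responseMean numeric(1), training response mean.
#' @slot responseSd numeric(1), training response SD (divisor `nTrain`).
#' @slot nTrain integer(1), number of training samples.
#' @slot dropped integer, original column indices removed because they had
#'   zero variance in the training block.
#' @slot markerNames character, names of the retained marker columns.
#'
#' @seealso [fitStandardizer()], [applyStandardizer()],
#'   [invertPredictions()]
#' @export
setClass("StandardizationStats",
  representation(
    columnMeans = "numeric",
    columnSds = "numeric",
    responseMean = "numeric",
    responseSd = "numeric",
    nTrain = "integer",
    dropped = "integer",
    markerNames = "character"
  )
)

setValidity("StandardizationStats", function(object) {
  msg <- character()
  if (length(object@columnMeans) != length(object@columnSds))
    msg <- c(msg, "columnMeans and columnSds must have equal length")
  if (any(object@columnSds <= 0))
    msg <- c(msg, "all column SDs must be strictly positive")
  if (length(object@nTrain) != 1L || object@nTrain < 2L)
    msg <- c(msg, "nTrain must be a single integer >= 2")
  if (length(object@responseSd) != 1L || object@responseSd <= 0)
    msg <- c(msg, "responseSd must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Candidate regularization-parameter sequence
#'
#' An ordered (strictly descending, strictly positive) sequence of candidate
#' penalty values \eqn{\lambda} together with the construction method and
#' its provenance. Two constructors exist: [conventionalGrid()] builds the
#' glmnet-style log-equally-spaced path between \eqn{\lambda_{max}} and
#' \eqn{\lambda_{min}}; [varianceRatioGrid()] maps log-spaced proportions of
#' explained phenotypic variance \eqn{R^2_l} to \eqn{\lambda_l} through a
#' variance-component ratio.
#'
#' @slot values numeric, strictly decreasing positive lambda values.
#' @slot method character(1), `"conventional"` or `"variance_ratio"`.
#' @slot nPoints integer(1), grid length.
#' @slot provenance list; for the conventional grid: `lambdaMax`,
#'   `lambdaMin`, `lambdaMinRatio`; for the variance-ratio grid: `r2` (the
#'   \eqn{R^2_l} sequence), `sY2` (phenotypic variance supplied), `m` (mean
#'   squared row norm \eqn{(1/n)\sum_i x_i^\top x_i}).
#'
#' @export
setClass("LambdaGrid",
  representation(
    values = "numeric",
    method = "character",
    nPoints = "integer",
    provenance = "list"
  )
)

setValidity("LambdaGrid", function(object) {
  msg <- character()
  v <- object@values
  if (length(v) != object@nPoints)
    msg <- c(msg, "length(values) must equal nPoints")
  if (any(!is.finite(v)) || any(v <= 0))
    msg <- c(msg, "all lambda values must be finite and > 0")
  if (length(v) > 1L && any(diff(v) >= 0))
    msg <- c(msg, "lambda values must be strictly decreasing")
  if (!object@method %in% c("conventional", "variance_ratio"))
    msg <- c(msg, "method must be 'conventional' or 'variance_ratio'")
  if (length(msg)) msg else TRUE
})

#' Penalized regression fit along a lambda path
#'
#' Intercepts and coefficient vectors of the elastic-net objective
#' \deqn{\frac{1}{2n}\sum_i (y_i - \beta_0 - x_i^\top\beta)^2 +
#'   \lambda\left[\frac{1-\alpha}{2}\|\beta\|_2^2 +
#'   \alpha\|\beta\|_1\right]}
#' fitted at every value of a descending lambda path. `alpha = 0` is ridge,
#' `alpha = 1` is the lasso.
#'
#' @slot alpha numeric(1), mixing parameter in `[0, 1]`.
#' @slot lambdas numeric, the fitted (descending) path.
#' @slot intercepts numeric, one per lambda.
#' @slot coefficients matrix, `p x length(lambdas)` coefficients on the
#'   scale of the supplied predictors.
#' @slot convergence list with `iterations`, `maxDelta` and `converged`
#'   per lambda (iterations are 0 for closed-form ridge solves).
#' @slot engine character(1), `"exact"` or `"cd"`.
#' @slot markerNames character, predictor names.
#' @slot objective list, per-lambda objective traces when requested.
#'
#' @seealso [fitPath()]
#' @export
setClass("PenalizedFit",
  representation(
    alpha = "numeric",
    lambdas = "numeric",
    intercepts = "numeric",
    coefficients = "matrix",
    convergence = "list",
    engine = "character",
    markerNames = "character",
    objective = "list"
  )
)

setValidity("PenalizedFit", function(object) {
  msg <- character()
  L <- length(object@lambdas)
  if (length(object@intercepts) != L)
    msg <- c(msg, "one intercept per lambda required")
  if (ncol(object@coefficients) != L)
    msg <- c(msg, "one coefficient column per lambda required")
  if (object@alpha < 0 || object@alpha > 1)
    msg <- c(msg, "alpha must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Inner cross-validation result over a lambda grid
#'
#' Per-fold validation losses for every candidate lambda and the selected
#' optimum. Losses are stored both as raw sums of squared errors and as
#' per-observation means; the selection criterion averages the
#' per-observation means across folds so folds of unequal size weigh
#' correctly.
#'
#' @slot grid the [LambdaGrid-class] searched.
#' @slot foldMse matrix `k x L`, per-observation mean validation squared
#'   error on the original response scale.
#' @slot foldSse matrix `k x L`, summed squared validation error.
#' @slot meanMse numeric, column means of `foldMse`.
#' @slot lambdaOpt numeric(1), selected lambda (minimum `meanMse`; ties go
#'   to the largest lambda).
#' @slot lambdaOptIndex integer(1), its position in the grid.
#' @slot foldAssignment integer, inner-fold label per training sample.
#' @slot seed integer(1), RNG seed used for fold construction.
#' @slot alpha numeric(1), mixing parameter used.
#'
#' @seealso [innerCV()]
#' @export
setClass("CVResult",
  representation(
    grid = "LambdaGrid",
    foldMse = "matrix",
    foldSse = "matrix",
    meanMse = "numeric",
    lambdaOpt = "numeric",
    lambdaOptIndex = "integer",
    foldAssignment = "integer",
    seed = "integer",
    alpha = "numeric"
  )
)

setValidity("CVResult", function(object) {
  msg <- character()
  L <- length(object@grid@values)
  if (ncol(object@foldMse) != L || length(object@meanMse) != L)
    msg <- c(msg, "loss dimensions must match the grid length")
  io <- object@lambdaOptIndex
  if (length(io) != 1L || io < 1L || io > L)
    msg <- c(msg, "lambdaOptIndex out of range")
  if (length(msg)) msg else TRUE
})

#' Final tuned model refit on a full training set
#'
#' A single-lambda [PenalizedFit-class] together with the
#' [StandardizationStats-class] of the training set it was fitted on, so
#' that held-out genotypes can be standardized and predictions returned on
#' the observed phenotype scale.
#'
#' @slot fit single-lambda [PenalizedFit-class] on the standardized scale.
#' @slot stats the training [StandardizationStats-class].
#' @slot lambda numeric(1), the tuned penalty.
#' @slot alpha numeric(1).
#'
#' @seealso [refitFull()]
#' @export
setClass("SelectedModel",
  representation(
    fit = "PenalizedFit",
    stats = "StandardizationStats",
    lambda = "numeric",
    alpha = "numeric"
  )
)

#' VanRaden genomic relationship matrix
#'
#' The marker-derived relationship matrix \eqn{G = ZZ^\top / c} with
#' \eqn{Z} the allele-frequency-centered dosage matrix and
#' \eqn{c = 2\sum_j p_j (1 - p_j)} (VanRaden method 1). Monomorphic markers
#' contribute zero to \eqn{Z} and are excluded from the denominator.
#'
#' @slot matrix square numeric matrix of genomic relationships.
#' @slot alleleFreqs numeric, per-marker allele frequency used for
#'   centering (estimated from the designated frequency rows).
#' @slot scaleConstant numeric(1), the denominator \eqn{2\sum p_j(1-p_j)}.
#' @slot polymorphic logical, per-marker indicator of inclusion.
#' @slot ids character, line identifiers (row/column names of `matrix`).
#'
#' @seealso [vanRadenG()]
#' @export
setClass("GenomicRelationship",
  representation(
    matrix = "matrix",
    alleleFreqs = "numeric",
    scaleConstant = "numeric",
    polymorphic = "logical",
    ids = "character"
  )
)

setValidity("GenomicRelationship", function(object) {
  msg <- character()
  G <- object@matrix
  if (nrow(G) != ncol(G))
    msg <- c(msg, "relationship matrix must be square")
  if (max(abs(G - t(G))) > 1e-10)
    msg <- c(msg, "relationship matrix must be symmetric within 1e-10")
  if (object@scaleConstant <= 0)
    msg <- c(msg, "scale constant must be positive")
  if (length(msg)) msg else TRUE
})

#' REML GBLUP fit
#'
#' Variance components, fixed mean and genomic BLUPs of the mixed model
#' \eqn{y_i = \mu + g_i + \epsilon_i}, \eqn{g \sim N(0, \sigma_g^2 G)},
#' estimated by spectral profile REML: the relationship matrix is
#' eigendecomposed once and the restricted log-likelihood is maximized over
#' the variance ratio \eqn{\delta = \sigma^2 / \sigma_g^2} by 1-D bounded
#' search on the log scale.
#'
#' @slot mu numeric(1), GLS estimate of the fixed mean.
#' @slot sigmaG2 numeric(1), genetic variance.
#' @slot sigmaE2 numeric(1), residual variance.
#' @slot delta numeric(1), \eqn{\sigma^2/\sigma_g^2}.
#' @slot h2 numeric(1), \eqn{\sigma_g^2/(\sigma_g^2+\sigma^2) = 1/(1+\delta)}.
#' @slot blups numeric, genomic BLUPs for all lines (phenotyped and not).
#' @slot trainIds character, lines whose phenotypes entered the fit.
#' @slot logLik numeric(1), restricted log-likelihood at the optimum.
#' @slot bracketed logical(1), whether a coarse grid scan bracketed the
#'   optimizer found by the line search.
#'
#' @seealso [remlFit()], [gblupPredict()]
#' @export
setClass("GblupFit",
  representation(
    mu = "numeric",
    sigmaG2 = "numeric",
    sigmaE2 = "numeric",
    delta = "numeric",
    h2 = "numeric",
    blups = "numeric",
    trainIds = "character",
    logLik = "numeric",
    bracketed = "logical"
  )
)

#' Simulation ground truth
#'
#' The generating quantities of a simulated quantitative trait: QTL
#' positions and effects, target and realized variance shares, error
#' variance, intercept and seed. The error variance is calibrated against
#' the sample variance of the genetic values so the realized genetic share
#' equals the target exactly on the generated sample.
#'
#' @slot qtlIndices integer, marker indices with nonzero effect.
#' @slot effects numeric, their additive effects.
#' @slot h2Target numeric(1), intended narrow-sense heritability.
#' @slot h2Realized numeric(1), `var(g) / (var(g) + sigmaE2)` on the sample.
#' @slot sigmaE2 numeric(1), error variance used.
#' @slot mu numeric(1), intercept.
#' @slot seed integer(1), RNG seed.
#'
#' @seealso [simulatePhenotype()]
#' @export
setClass("SimTruth",
  representation(
    qtlIndices = "integer",
    effects = "numeric",
    h2Target = "numeric",
    h2Realized = "numeric",
    sigmaE2 = "numeric",
    mu = "numeric",
    seed = "integer"
  )
)

#' Outer cross-validation evaluation report
#'
#' Per-fold prediction metrics (Pearson correlation and NRMSE on the
#' observed phenotype scale) for each compared method under identical outer
#' folds, plus the tuned lambda per fold for grid-based methods.
#'
#' @slot perFold data.frame with columns `method`, `trait`, `fold`, `cor`,
#'   `nrmse`, `lambdaOpt` (NA for GBLUP).
#' @slot trait character(1), trait label.
#' @slot foldAssignment integer, outer-fold label per sample.
#' @slot methods character, the compared methods.
#' @slot seed integer(1), top-level seed.
#' @slot alpha numeric(1), mixing parameter for grid methods.
#'
#' @seealso [outerEvaluate()], [lambdaRatioDiagnostic()],
#'   [aggregateReports()]
#' @export
setClass("EvaluationReport",
  representation(
    perFold = "data.frame",
    trait = "character",
    foldAssignment = "integer",
    methods = "character",
    seed = "integer",
    alpha = "numeric"
  )
)
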