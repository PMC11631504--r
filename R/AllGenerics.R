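#' Extract the lambda values of a grid or fit
#'
#' @param object a [LambdaGrid-class], [PenalizedFit-class] or
#'   [CVResult-class].
#' @return numeric vector of lambda values (descending).
#' @export
setGeneric("lambdaValues", function(object) standardGeneric("lambdaValues"))

#' Grid construction method tag
#'
#' @param object a [LambdaGrid-class] or [CVResult-class].
#' @return `"conventional"` or `"variance_ratio"`.
#' @export
setGeneric("gridMethod", function(object) standardGeneric("gridMethod"))

#' Selected optimal lambda
#'
#' @param object a [CVResult-class] or [SelectedModel-class].
#' @return numeric(1), the tuned penalty.
#' @export
setGeneric("lambdaOpt", function(object) standardGeneric("lambdaOpt"))

#' Genomic relationship matrix accessor
#'
#' @param object a [GenomicRelationship-class].
#' @return the square numeric relationship matrix.
#' @export
setGeneric("relMatrix", function(object) standardGeneric("relMatrix"))

#' Estimated narrow-sense heritability
#'
#' @param object a [GblupFit-class] or [SimTruth-class] (for the latter the
#'   realized genetic variance share is returned).
#' @return numeric(1) in `[0, 1]`.
#' @export
setGeneric("heritability", function(object) standardGeneric("heritability"))

#' Per-fold evaluation metrics
#'
#' @param object an [EvaluationReport-class].
#' @return data.frame, one row per method x fold.
#' @export
setGeneric("perFoldMetrics", function(object) standardGeneric("perFoldMetrics"))

## -- accessor methods ------------------------------------------------------

#' @describeIn lambdaValues grid values
setMethod("lambdaValues", "LambdaGrid", function(object) object@values)

#' @describeIn lambdaValues fitted path
setMethod("lambdaValues", "PenalizedFit", function(object) object@lambdas)

#' @describeIn lambdaValues values of the searched grid
setMethod("lambdaValues", "CVResult", function(object) object@grid@values)

#' @describeIn gridMethod construction tag
setMethod("gridMethod", "LambdaGrid", function(object) object@method)

#' @describeIn gridMethod tag of the searched grid
setMethod("gridMethod", "CVResult", function(object) object@grid@method)

#' @describeIn lambdaOpt tuned penalty
setMethod("lambdaOpt", "CVResult", function(object) object@lambdaOpt)

#' @describeIn lambdaOpt penalty of the refitted model
setMethod("lambdaOpt", "SelectedModel", function(object) object@lambda)

#' @describeIn relMatrix the G matrix
setMethod("relMatrix", "GenomicRelationship", function(object) object@matrix)

#' @describeIn heritability REML estimate
setMethod("heritability", "GblupFit", function(object) object@h2)

#' @describeIn heritability realized simulated share
setMethod("heritability", "SimTruth", function(object) object@h2Realized)

#' @describeIn perFoldMetrics per-fold table
setMethod("perFoldMetrics", "EvaluationReport", function(object) object@perFold)

#' Coefficients of a penalized fit
#'
#' @param object a [PenalizedFit-class].
#' @param ... unused.
#' @return matrix `p x L` of coefficients, one column per lambda.
#' @export
setMethod("coef", "PenalizedFit", function(object, ...) object@coefficients)

## -- show methods ----------------------------------------------------------

setMethod("show", "LambdaGrid", function(object) {
  v <- object@values
  cat(sprintf("LambdaGrid [%s], %d values in [%.4g, %.4g]\n",
              object@method, length(v), min(v), max(v)))
})

setMethod("show", "PenalizedFit", function(object) {
  cat(sprintf("PenalizedFit: alpha = %g, %d predictors, %d lambda value(s), engine = %s\n",
              object@alpha, nrow(object@coefficients),
              length(object@lambdas), object@engine))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf(
    "CVResult [%s]: %d folds x %d lambdas; lambda.opt = %.6g (index %d)\n",
    object@grid@method, nrow(object@foldMse),
    length(object@grid@values), object@lambdaOpt, object@lambdaOptIndex))
})

setMethod("show", "SelectedModel", function(object) {
  cat(sprintf("SelectedModel: alpha = %g, lambda = %.6g, %d markers\n",
              object@alpha, object@lambda, length(object@stats@columnSds)))
})

setMethod("show", "GenomicRelationship", function(object) {
  cat(sprintf(
    "GenomicRelationship: %d lines, %d/%d polymorphic markers, mean diag = %.3f\n",
    nrow(object@matrix), sum(object@polymorphic), length(object@polymorphic),
    mean(diag(object@matrix))))
})

setMethod("show", "GblupFit", function(object) {
  cat(sprintf(
    "GblupFit: mu = %.4g, sigmaG2 = %.4g, sigmaE2 = %.4g, h2 = %.3f (%d training lines)\n",
    object@mu, object@sigmaG2, object@sigmaE2, object@h2,
    length(object@trainIds)))
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf(
    "SimTruth: %d QTL, target h2 = %.2f, realized share = %.3f, sigmaE2 = %.4g\n",
    length(object@qtlIndices), object@h2Target, object@h2Realized,
    object@sigmaE2))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport for trait '%s': methods = %s, %d folds\n",
              object@trait, paste(object@methods, collapse = ", "),
              max(object@foldAssignment)))
})
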