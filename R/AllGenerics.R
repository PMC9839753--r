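#' Extract factor loadings
#'
#' Generic accessor for the loading matrix of a [FactorSolution] or [CfaFit].
#' The default method is `stats::loadings`.
#'
#' @param x an object with loadings.
#' @param ... unused.
#' @return a variables x factors numeric matrix.
#' @export
setGeneric("loadings")

#' @rdname loadings
#' @export
setMethod("loadings", "FactorSolution", function(x, ...) x@loadings)

#' @rdname loadings
#' @export
setMethod("loadings", "CfaFit", function(x, ...) x@loadings)

#' Extract per-variable uniquenesses
#'
#' @param x a [FactorSolution].
#' @return named numeric vector, the diagonal of \eqn{U^2}.
#' @export
setGeneric("uniquenesses", function(x) standardGeneric("uniquenesses"))

#' @rdname uniquenesses
#' @export
setMethod("uniquenesses", "FactorSolution", function(x) x@uniquenesses)

#' Per-factor explained variance
#'
#' The variance a factor explains is the sum of its squared loadings over
#' all variables, \eqn{EV_f = \sum_v l_{v,f}^2}.  For standardized variables
#' `EV / nrow(loadings)` is the fraction of total variance.
#'
#' @param x a loading matrix or a [FactorSolution].
#' @param percent logical; if `TRUE` return percent of total variance
#'   (`100 * EV / number of variables`) instead of raw sums.
#' @return numeric vector, one value per factor.
#' @examples
#' explainedVariance(cbind(a = rep(0.5, 4)))  # 4 * 0.25 = 1
#' @export
setGeneric("explainedVariance",
           function(x, percent = FALSE) standardGeneric("explainedVariance"))

#' @rdname explainedVariance
#' @export
setMethod("explainedVariance", "matrix", function(x, percent = FALSE) {
    ev <- colSums(x^2)
    if (percent) 100 * ev / nrow(x) else ev
})

#' @rdname explainedVariance
#' @export
setMethod("explainedVariance", "FactorSolution", function(x, percent = FALSE) {
    if (percent) 100 * x@explainedVariance / nrow(x@loadings)
    else x@explainedVariance
})

#' Number of factors in a solution
#'
#' @param x a [FactorSolution].
#' @return integer count of factors.
#' @export
setGeneric("nFactors", function(x) standardGeneric("nFactors"))

#' @rdname nFactors
#' @export
setMethod("nFactors", "FactorSolution", function(x) x@nFactors)

#' Consensus index matrix accessor
#'
#' @param x a [ConsensusMatrix].
#' @return symmetric variables x variables matrix of consensus indices.
#' @export
setGeneric("consensusIndices", function(x) standardGeneric("consensusIndices"))

#' @rdname consensusIndices
#' @export
setMethod("consensusIndices", "ConsensusMatrix", function(x) x@indices)
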