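#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
NULL

#' BehavioralTable: a subjects-by-variables behavioral data container
#'
#' `BehavioralTable` extends [SummarizedExperiment::SummarizedExperiment]
#' with the layout used throughout this package: behavioral variables as rows
#' and subjects as columns of the `"values"` assay.  Per-variable metadata
#' (category, error-measure / composite / adjusted flags) live in `rowData`;
#' per-subject confounds (age, gender) and family identifiers live in
#' `colData`.  Missing entries are stored as `NA` in the assay.
#'
#' Most analysis functions in the package consume the transposed
#' subjects-by-variables matrix returned by [behavioralValues()].
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @seealso [BehavioralTable()] for construction, [behavioralValues()],
#'   [variableMeta()], [confounds()], [familyId()], [missingMask()].
#' @export
setClass("BehavioralTable", contains = "SummarizedExperiment")

setValidity("BehavioralTable", function(object) {
    msg <- character()
    if (!"values" %in% assayNames(object))
        msg <- c(msg, "assay 'values' is required")
    else if (!is.numeric(assay(object, "values")))
        msg <- c(msg, "assay 'values' must be numeric")
    need <- c("isErrorMeasure", "isComposite", "isAdjusted")
    have <- need %in% colnames(rowData(object))
    if (!all(have))
        msg <- c(msg, paste0("rowData must contain logical column(s): ",
                             paste(need[!have], collapse = ", ")))
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "variable (row) names must be unique")
    if (length(msg)) msg else TRUE
})

#' FactorSolution: an orthogonal factor model for standardized variables
#'
#' Holds the loading matrix \eqn{L} (variables x factors), the per-variable
#' uniquenesses (diagonal of \eqn{U^2}), the per-factor explained variance
#' \eqn{EV_f = \sum_v l_{v,f}^2}, and fitting metadata.  On standardized data
#' the model-implied covariance is \eqn{\Sigma = L L' + U^2}.
#'
#' @slot loadings variables x factors numeric matrix.
#' @slot uniquenesses nonnegative numeric vector, one per variable.
#' @slot explainedVariance per-factor sums of squared loadings.
#' @slot nFactors integer, number of factors.
#' @slot rotated logical, whether a varimax rotation has been applied.
#' @slot converged logical, optimizer convergence status.
#' @slot nObs integer, number of subjects behind the fitted covariance.
#' @slot discrepancy achieved maximum-likelihood discrepancy value.
#' @seealso [fitMlFactors()], [efa()], [varimaxRotate()],
#'   [reconstructCovariance()], [bartlettScores()].
#' @export
setClass("FactorSolution",
    representation(loadings = "matrix", uniquenesses = "numeric",
                   explainedVariance = "numeric", nFactors = "integer",
                   rotated = "logical", converged = "logical",
                   nObs = "integer", discrepancy = "numeric"))

setValidity("FactorSolution", function(object) {
    msg <- character()
    L <- object@loadings
    if (ncol(L) != object@nFactors)
        msg <- c(msg, "ncol(loadings) must equal nFactors")
    if (length(object@uniquenesses) != nrow(L))
        msg <- c(msg, "one uniqueness per variable is required")
    if (any(object@uniquenesses < 0))
        msg <- c(msg, "uniquenesses must be nonnegative")
    ev <- colSums(L^2)
    if (length(object@explainedVariance) != ncol(L) ||
        any(abs(ev - object@explainedVariance) > 1e-8))
        msg <- c(msg, "explainedVariance must equal colSums(loadings^2)")
    if (length(msg)) msg else TRUE
})

#' ConsensusMatrix: pairwise co-clustering evidence over resampled K-means
#'
#' For every pair of variables, the consensus index is the fraction of times
#' the pair was clustered together out of the times both were drawn in the
#' same variable subsample.
#'
#' @slot indices variables x variables symmetric matrix of consensus indices
#'   in \[0, 1\], unit diagonal.
#' @slot coSampleCounts times each pair appeared in the same subsample.
#' @slot togetherCounts times each pair landed in the same cluster.
#' @slot K integer, number of clusters used.
#' @slot nIterations number of resampling iterations.
#' @slot fraction fraction of variables drawn per iteration.
#' @seealso [consensusCluster()], [consensusScore()], [consensusCdfAuc()],
#'   [clusterConsensus()], [finalLabels()].
#' @export
setClass("ConsensusMatrix",
    representation(indices = "matrix", coSampleCounts = "matrix",
                   togetherCounts = "matrix", K = "integer",
                   nIterations = "integer", fraction = "numeric"))

setValidity("ConsensusMatrix", function(object) {
    msg <- character()
    M <- object@indices
    if (nrow(M) != ncol(M) || max(abs(M - t(M))) > 1e-12)
        msg <- c(msg, "indices must be a symmetric square matrix")
    if (any(M < 0 | M > 1))
        msg <- c(msg, "consensus indices must lie in [0, 1]")
    if (any(abs(diag(M) - 1) > 1e-12))
        msg <- c(msg, "indices must have a unit diagonal")
    if (!all(dim(M) == dim(object@coSampleCounts)))
        msg <- c(msg, "coSampleCounts must match indices in shape")
    if (object@K < 2L) msg <- c(msg, "K must be at least 2")
    if (length(msg)) msg else TRUE
})

#' CfaPattern: free/fixed loading pattern for confirmatory factor analysis
#'
#' @slot freeMask variables x factors logical matrix; `TRUE` marks a loading
#'   that is estimated, `FALSE` one fixed to zero.  Variables without any
#'   free loading are excluded from the model at construction.
#' @slot factorCovFree logical; whether factor covariances are estimated
#'   (factor variances are always fixed to 1).
#' @slot startLoadings numeric matrix of starting values (same shape as
#'   `freeMask`), typically the source EFA loadings.
#' @slot dropped names of variables excluded for lacking an indicator role.
#' @seealso [patternFromEfa()], [fitCfa()].
#' @export
setClass("CfaPattern",
    representation(freeMask = "matrix", factorCovFree = "logical",
                   startLoadings = "matrix", dropped = "character"))

setValidity("CfaPattern", function(object) {
    msg <- character()
    m <- object@freeMask
    if (!is.logical(m)) msg <- c(msg, "freeMask must be logical")
    else {
        if (any(colSums(m) < 1))
            msg <- c(msg, "every factor needs at least one free indicator")
        if (any(rowSums(m) < 1))
            msg <- c(msg, "variables without a free loading must be dropped")
    }
    if (!all(dim(object@startLoadings) == dim(m)))
        msg <- c(msg, "startLoadings must match freeMask in shape")
    if (length(msg)) msg else TRUE
})

#' CfaFit: a fitted confirmatory factor model with fit indices
#'
#' @slot loadings estimated loadings (zeros where fixed).
#' @slot residualVariances estimated residual (unique) variances.
#' @slot factorCov estimated factor covariance matrix (unit diagonal).
#' @slot implied model-implied covariance matrix at the optimum.
#' @slot sampleCov sample covariance (correlation) matrix analyzed.
#' @slot fml minimized ML discrepancy value.
#' @slot chiSquare,df model chi-square and degrees of freedom.
#' @slot baselineChiSquare,baselineDf independence-model baseline.
#' @slot cfi,tli,rmsea,srmr fit indices; `rmseaCi90` is the 90% interval.
#' @slot nObs number of observations; `converged` the optimizer status.
#' @seealso [fitCfa()], [fitIndices()], [baselineModel()].
#' @export
setClass("CfaFit",
    representation(loadings = "matrix", residualVariances = "numeric",
                   factorCov = "matrix", implied = "matrix",
                   sampleCov = "matrix", fml = "numeric",
                   chiSquare = "numeric", df = "integer",
                   baselineChiSquare = "numeric", baselineDf = "integer",
                   cfi = "numeric", tli = "numeric", rmsea = "numeric",
                   rmseaCi90 = "numeric", srmr = "numeric",
                   nObs = "integer", converged = "logical"))

#' SyntheticSpec: ground-truth recipe for synthetic behavioral tables
#'
#' Defines a population orthogonal factor model: variables are weighted sums
#' of uncorrelated standard-normal factor scores plus Gaussian noise with
#' variable-specific variance, optionally with linear age/gender confound
#' effects, MCAR missingness (strictly below 10%), and a family structure
#' used only by the family-preserving splitter.
#'
#' @slot nSubjects number of subjects to draw.
#' @slot loadings variables x factors matrix of population loadings.
#' @slot uniquenesses per-variable noise variances (diagonal of \eqn{U^2}).
#' @slot confoundEffects variables x 2 matrix of age and gender coefficients.
#' @slot missingRate MCAR missingness fraction in \[0, 0.10).
#' @slot familySizes positive integers summing to `nSubjects`.
#' @slot seed integer RNG seed; generation is bit-reproducible given the spec.
#' @seealso [syntheticSpec()], [generateFactorData()].
#' @export
setClass("SyntheticSpec",
    representation(nSubjects = "integer", loadings = "matrix",
                   uniquenesses = "numeric", confoundEffects = "matrix",
                   missingRate = "numeric", familySizes = "integer",
                   seed = "integer"))

setValidity("SyntheticSpec", function(object) {
    msg <- character()
    V <- nrow(object@loadings)
    if (length(object@uniquenesses) != V)
        msg <- c(msg, "one uniqueness per variable is required")
    if (any(object@uniquenesses < 0))
        msg <- c(msg, "uniquenesses must be nonnegative")
    if (!all(dim(object@confoundEffects) == c(V, 2L)))
        msg <- c(msg, "confoundEffects must be a variables x 2 matrix")
    if (object@missingRate < 0 || object@missingRate >= 0.10)
        msg <- c(msg, "missingRate must lie in [0, 0.10)")
    if (any(object@familySizes < 1L))
        msg <- c(msg, "familySizes must be positive")
    if (sum(object@familySizes) != object@nSubjects)
        msg <- c(msg, "familySizes must sum to nSubjects")
    if (length(msg)) msg else TRUE
})
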