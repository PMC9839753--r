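#' Build a SyntheticSpec
#'
#' Convenience constructor for the ground-truth recipe behind
#' [generateFactorData()].  The default loading layout is block simple
#' structure: `nFactors` blocks of `varsPerFactor` variables, each loading
#' `loading` on its own factor and 0 elsewhere, with uniquenesses chosen so
#' every variable has unit population variance
#' (`uniqueness = 1 - loading^2`).
#'
#' @param nSubjects number of subjects.
#' @param loadings optional explicit variables x factors loading matrix;
#'   overrides the block layout.
#' @param nFactors,varsPerFactor,loading block-structure shortcut used when
#'   `loadings` is not given.
#' @param uniquenesses per-variable noise variances; default
#'   `1 - rowSums(loadings^2)` (floored at 0).
#' @param confoundEffects variables x 2 matrix of age and gender slopes;
#'   default all zero.
#' @param missingRate MCAR missingness rate in \[0, 0.10); default 0.
#' @param familySizes positive integers summing to `nSubjects`; default a
#'   mix of singletons and sibling pairs/triples.
#' @param seed integer RNG seed.
#' @return a [SyntheticSpec-class] object.
#' @examples
#' spec <- syntheticSpec(200, nFactors = 3, varsPerFactor = 5, seed = 1)
#' dim(spec@loadings)
#' @export
syntheticSpec <- function(nSubjects, loadings = NULL, nFactors = 4,
                          varsPerFactor = 10, loading = 0.7,
                          uniquenesses = NULL, confoundEffects = NULL,
                          missingRate = 0, familySizes = NULL, seed = 1) {
    if (is.null(loadings)) {
        loadings <- matrix(0, nFactors * varsPerFactor, nFactors)
        for (f in seq_len(nFactors))
            loadings[(f - 1L) * varsPerFactor + seq_len(varsPerFactor), f] <-
                loading
    }
    loadings <- as.matrix(loadings)
    V <- nrow(loadings)
    if (is.null(rownames(loadings)))
        rownames(loadings) <- sprintf("v%02d", seq_len(V))
    if (is.null(colnames(loadings)))
        colnames(loadings) <- paste0("F", seq_len(ncol(loadings)))
    if (is.null(uniquenesses))
        uniquenesses <- pmax(1 - rowSums(loadings^2), 0)
    if (is.null(confoundEffects))
        confoundEffects <- matrix(0, V, 2)
    colnames(confoundEffects) <- c("age", "gender")
    if (is.null(familySizes))
        familySizes <- defaultFamilySizes(nSubjects)
    new("SyntheticSpec", nSubjects = as.integer(nSubjects),
        loadings = loadings, uniquenesses = as.numeric(uniquenesses),
        confoundEffects = as.matrix(confoundEffects),
        missingRate = as.numeric(missingRate),
        familySizes = as.integer(familySizes), seed = as.integer(seed))
}

# Singleton / pair / triple mix covering n subjects (deterministic).
defaultFamilySizes <- function(n) {
    sizes <- integer(0)
    left <- n
    while (left > 0L) {
        s <- c(1L, 2L, 1L, 3L, 2L, 1L)[(length(sizes) %% 6L) + 1L]
        s <- min(s, left)
        sizes <- c(sizes, s)
        left <- left - s
    }
    sizes
}

#' Generate a behavioral table from a planted factor model
#'
#' Draws i.i.d. standard-normal factor scores \eqn{F} (orthogonal in the
#' population), Gaussian noise with variable-specific variance, integer ages
#' uniform on 22--37 and Bernoulli(0.5) gender, and assembles
#' \eqn{x_{i,v} = \sum_f l_{v,f} F_{f,i} + \beta^{age}_v age_i +
#' \beta^{gen}_v gender_i + \epsilon_{i,v}}.  MCAR missingness is planted at
#' the spec's rate via [plantMissingness()].  Output is bit-reproducible
#' given the spec (including its seed).
#'
#' @param spec a [SyntheticSpec-class].
#' @param ageRange integer range ages are drawn from.
#' @return a list with `table` (a [BehavioralTable-class]) and `truth`
#'   (list: `factorScores` subjects x factors, `clusterLabels` per-variable
#'   block membership = factor with the largest absolute loading,
#'   `confounds` data frame).
#' @examples
#' out <- generateFactorData(syntheticSpec(100, nFactors = 2,
#'                                         varsPerFactor = 4, seed = 7))
#' dim(behavioralValues(out$table))
#' @export
generateFactorData <- function(spec, ageRange = 22:37) {
    stopifnot(is(spec, "SyntheticSpec"))
    validObject(spec)
    n <- spec@nSubjects
    L <- spec@loadings
    V <- nrow(L)
    k <- ncol(L)
    withSeed(spec@seed, {
        FS <- matrix(stats::rnorm(n * k), n, k,
                     dimnames = list(NULL, colnames(L)))
        eps <- matrix(stats::rnorm(n * V), n, V)
        eps <- eps * rep(sqrt(spec@uniquenesses), each = n)
        age <- sample(ageRange, n, replace = TRUE)
        gender <- stats::rbinom(n, 1L, 0.5)
        x <- FS %*% t(L) +
            outer(age, spec@confoundEffects[, "age"]) +
            outer(gender, spec@confoundEffects[, "gender"]) + eps
        colnames(x) <- rownames(L)
        rownames(x) <- sprintf("S%04d", seq_len(n))
        famId <- rep(sprintf("fam%04d", seq_along(spec@familySizes)),
                     times = spec@familySizes)
        labels <- apply(abs(L), 1L, which.max)
        tab <- BehavioralTable(
            x,
            variableMeta = data.frame(
                category = paste0("block", labels),
                isErrorMeasure = FALSE, isComposite = FALSE,
                isAdjusted = FALSE),
            confounds = data.frame(age = age, gender = gender),
            familyId = famId)
        if (spec@missingRate > 0)
            tab <- plantMissingness(tab, spec@missingRate,
                                    seed = spec@seed + 1L)
        list(table = tab,
             truth = list(factorScores = FS,
                          clusterLabels = stats::setNames(labels,
                                                          rownames(L)),
                          confounds = data.frame(age = age,
                                                 gender = gender)))
    })
}

#' Plant MCAR missingness, capped strictly below 10% per variable
#'
#' Each entry is masked independently with probability `rate`; any variable
#' that would reach a 10% missing fraction has excess masked entries
#' restored at random, mirroring the usual behavioral-data inclusion
#' criterion of keeping variables with under 10% missing values.
#'
#' @param table a [BehavioralTable-class].
#' @param rate missingness probability, in \[0, 0.10).
#' @param seed integer RNG seed.
#' @return the table with `NA` planted in its assay.
#' @export
plantMissingness <- function(table, rate, seed) {
    if (rate < 0 || rate >= 0.10)
        stop("'rate' must lie in [0, 0.10)")
    if (rate == 0) return(table)
    vals <- behavioralValues(table)
    n <- nrow(vals)
    maxMiss <- ceiling(n * 0.10 - 1e-9) - 1L  # largest m with m/n < 0.10
    withSeed(seed, {
        mask <- matrix(stats::runif(length(vals)) < rate, n, ncol(vals))
        for (v in seq_len(ncol(vals))) {
            idx <- which(mask[, v])
            if (length(idx) > maxMiss)
                mask[sample(idx, length(idx) - maxMiss), v] <- FALSE
        }
        vals[mask] <- NA_real_
        setBehavioralValues(table, vals)
    })
}

#' Generate a pure-noise matrix for parallel analysis
#'
#' Fills an `nSubjects` x `nVariables` matrix with i.i.d. standard-normal
#' draws — the null reference whose apparent shared variance calibrates how
#' many factors real data support.
#'
#' @param nSubjects,nVariables positive dimensions.
#' @param seed integer RNG seed; the same seed reproduces the same matrix.
#' @return a numeric matrix.
#' @export
generateNullMatrix <- function(nSubjects, nVariables, seed) {
    stopifnot(nSubjects >= 1, nVariables >= 1)
    withSeed(seed,
             matrix(stats::rnorm(nSubjects * nVariables),
                    as.integer(nSubjects), as.integer(nVariables)))
}
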