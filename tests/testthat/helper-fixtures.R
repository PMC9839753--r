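# Shared fixtures and independent oracles used across the suite.

# Planted block-structure dataset: k factors, varsPerFactor variables each,
# unit-variance variables; returns the standardized data matrix plus truth.
makePlantedData <- function(nSubjects, nFactors, varsPerFactor, loading,
                            seed, missingRate = 0) {
    spec <- syntheticSpec(nSubjects, nFactors = nFactors,
                          varsPerFactor = varsPerFactor, loading = loading,
                          missingRate = missingRate, seed = seed)
    out <- generateFactorData(spec)
    tab <- out$table
    x <- if (anyNA(behavioralValues(tab))) NULL
         else behavioralValues(zscoreTable(tab))
    list(spec = spec, table = tab, truth = out$truth, x = x)
}

# Tucker congruence between two loading vectors.
congruence <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))

# All permutations of 1..n as rows.
allPerms <- function(n) {
    if (n == 1L) return(matrix(1L))
    sub <- allPerms(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i)
        cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))))
}

# All set partitions of n items as canonical integer label vectors
# (restricted growth strings).
allPartitions <- function(n) {
    res <- list()
    rec <- function(labels, maxLab) {
        if (length(labels) == n) {
            res[[length(res) + 1L]] <<- labels
            return(invisible())
        }
        for (l in seq_len(maxLab + 1L)) rec(c(labels, l), max(maxLab, l))
    }
    rec(integer(0), 0L)
    res
}

# Pair-counting "index" term of the Rand statistics.
pairIndex <- function(a, b) sum(choose(table(a, b), 2))

# ARI by direct permutation averaging: the chance term is the mean index
# over all relabelings of b (exact for small n).
ariPermOracle <- function(a, b, perms) {
    obs <- pairIndex(a, b)
    expd <- mean(apply(perms, 1L, function(p) pairIndex(a, b[p])))
    mx <- (sum(choose(table(a), 2)) + sum(choose(table(b), 2))) / 2
    if (abs(mx - expd) < 1e-13) return(1)
    (obs - expd) / (mx - expd)
}

miOf <- function(a, b) {
    tab <- table(a, b)
    n <- length(a)
    pij <- tab / n
    ai <- rowSums(tab)
    bj <- colSums(tab)
    nz <- tab > 0
    sum(pij[nz] * log(pij[nz] / (outer(ai, bj) / n^2)[nz]))
}

entropyOf <- function(a) {
    p <- table(a) / length(a)
    -sum(p * log(p))
}

# Expected MI under the permutation model via dhyper-weighted summation
# over the hypergeometric support (independent of the package's
# lgamma-based evaluation).
emiHyperOracle <- function(a, b) {
    tab <- table(a, b)
    n <- length(a)
    ai <- rowSums(tab)
    bj <- colSums(tab)
    emi <- 0
    for (i in seq_along(ai)) {
        for (j in seq_along(bj)) {
            lo <- max(1, ai[i] + bj[j] - n)
            hi <- min(ai[i], bj[j])
            nij <- lo:hi
            pr <- stats::dhyper(nij, bj[j], n - bj[j], ai[i])
            emi <- emi + sum(pr * (nij / n) *
                                 log(n * nij / (ai[i] * bj[j])))
        }
    }
    emi
}

amiHyperOracle <- function(a, b) {
    emi <- emiHyperOracle(a, b)
    denom <- max(entropyOf(a), entropyOf(b)) - emi
    if (abs(denom) < 1e-14) return(0)
    (miOf(a, b) - emi) / denom
}

amiPermOracle <- function(a, b, perms) {
    emi <- mean(apply(perms, 1L, function(p) miOf(a, b[p])))
    denom <- max(entropyOf(a), entropyOf(b)) - emi
    if (abs(denom) < 1e-13) return(0)
    (miOf(a, b) - emi) / denom
}

# Hand-built ConsensusMatrix with prescribed upper-triangle indices.
consensusMatrixFromValues <- function(vals, K) {
    m <- (1 + sqrt(1 + 8 * length(vals))) / 2   # vals fill upper triangle
    stopifnot(m == round(m))
    idx <- diag(m)
    idx[upper.tri(idx)] <- vals
    idx <- idx + t(idx) - diag(m)
    diag(idx) <- 1
    counts <- matrix(100L, m, m)
    new("ConsensusMatrix", indices = idx, coSampleCounts = counts,
        togetherCounts = round(counts * idx), K = as.integer(K),
        nIterations = 100L, fraction = 0.8)
}

# Varimax criterion (sum over factors of the variance of squared loadings).
varimaxCriterion <- function(L) {
    sq <- L^2
    sum(apply(sq, 2L, function(col) mean((col - mean(col))^2)))
}
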