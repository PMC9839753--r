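#' Resampling consensus clustering of variables
#'
#' Repeatedly subsamples a fraction of the variables, K-means-clusters them
#' (each variable represented by its vector over subjects, with `nInit`
#' random restarts keeping the best within-cluster sum of squares), and
#' tallies for every variable pair how often it was clustered together out
#' of the times both were drawn.  The ratio is the consensus index.
#'
#' @param data subjects x variables standardized matrix.
#' @param K number of clusters (>= 2).
#' @param nIter resampling iterations (default 1000).
#' @param fraction fraction of variables per subsample (default 0.8).
#' @param nInit K-means restarts per iteration (default 10).
#' @param seed integer RNG seed.
#' @param features `"subjects"` (default; cluster columns of `data`) or
#'   `"correlation"` (cluster rows of the correlation matrix).
#' @return a [ConsensusMatrix-class].
#' @export
consensusCluster <- function(data, K, nIter = 1000, fraction = 0.8,
                             nInit = 10, seed,
                             features = c("subjects", "correlation")) {
    features <- match.arg(features)
    if (K < 2) stop("'K' must be at least 2")
    if (fraction <= 0 || fraction > 1) stop("'fraction' must be in (0, 1]")
    X <- if (features == "subjects") t(data) else stats::cor(data)
    V <- nrow(X)
    if (K > V) stop("more clusters than variables")
    m <- max(K, round(fraction * V))
    together <- matrix(0L, V, V)
    cosample <- matrix(0L, V, V)
    withSeed(seed, {
        for (it in seq_len(nIter)) {
            s <- sample(V, m)
            cl <- safeKmeans(X[s, , drop = FALSE], K, nInit)$cluster
            cosample[s, s] <- cosample[s, s] + 1L
            together[s, s] <- together[s, s] +
                (outer(cl, cl, "==") * 1L)
        }
    })
    never <- cosample == 0 & upper.tri(cosample)
    if (any(never))
        warning(sum(never), " variable pair(s) never co-sampled; ",
                "their consensus indices are set to 0")
    idx <- ifelse(cosample > 0, together / pmax(cosample, 1L), 0)
    diag(idx) <- 1
    vn <- colnames(data) %||% paste0("v", seq_len(V))
    dimnames(idx) <- list(vn, vn)
    new("ConsensusMatrix", indices = idx, coSampleCounts = cosample,
        togetherCounts = together, K = as.integer(K),
        nIterations = as.integer(nIter), fraction = fraction)
}

#' @describeIn ConsensusMatrix-class compact display.
#' @param object a `ConsensusMatrix`.
#' @export
setMethod("show", "ConsensusMatrix", function(object) {
    cat("ConsensusMatrix: ", nrow(object@indices), " variables, K = ",
        object@K, " (", object@nIterations, " iterations, ",
        sprintf("%.0f%%", 100 * object@fraction), " of variables)\n",
        sep = "")
    v <- upperTriVals(object@indices)
    cat(sprintf("  indices: median %.3f | CS = %.3f\n",
                stats::median(v), consensusScore(object)))
})

#' Empirical CDF and area under the CDF of the consensus indices
#'
#' The empirical distribution of the off-diagonal consensus indices
#' diagnoses clustering quality: under perfect consensus all indices sit at
#' 0 or 1 and the CDF is a step function.  The AUC is the integral of the
#' (right-continuous) empirical CDF over \[0, 1\]; it levels off once K
#' reaches the true cluster count.
#'
#' @param M a [ConsensusMatrix-class].
#' @return list with `cdf` (data frame `value`, `fraction` of indices at or
#'   below the value) and `auc` in \[0, 1\].
#' @examples
#' # half the indices at 0 and half at 1 give AUC = 0.5
#' @export
consensusCdfAuc <- function(M) {
    vals <- upperTriVals(consensusIndices(M))
    xs <- sort(unique(vals))
    frac <- cumsum(tabulate(match(sort(vals), xs), length(xs))) /
        length(vals)
    auc <- sum(frac * (c(xs[-1L], 1) - xs))
    list(cdf = data.frame(value = xs, fraction = frac), auc = auc)
}

#' Change in consensus AUC across cluster counts
#'
#' @param aucs named numeric vector of AUC values for consecutive K.
#' @param type `"relative"` (default; change divided by the previous AUC)
#'   or `"absolute"`.
#' @return numeric vector of the same length: the first entry is the first
#'   AUC itself, subsequent entries the change to the next K.
#' @export
deltaAuc <- function(aucs, type = c("relative", "absolute")) {
    type <- match.arg(type)
    if (length(aucs) < 1L) return(numeric(0))
    d <- diff(aucs)
    if (type == "relative") d <- d / utils::head(aucs, -1L)
    stats::setNames(c(aucs[1L], d), names(aucs))
}

#' Cluster consensus: within-cluster mean consensus index
#'
#' @param M a [ConsensusMatrix-class].
#' @param labels per-variable cluster ids covering all variables.
#' @return named numeric vector, one mean per cluster; singleton clusters
#'   are defined as 1 with a warning.
#' @export
clusterConsensus <- function(M, labels) {
    idx <- consensusIndices(M)
    if (length(labels) != nrow(idx))
        stop("'labels' must cover all variables")
    if (anyNA(labels)) stop("'labels' must not contain missing ids")
    out <- vapply(sort(unique(labels)), function(cl) {
        members <- which(labels == cl)
        if (length(members) == 1L) {
            warning("cluster ", cl, " is a singleton; consensus set to 1")
            return(1)
        }
        sub <- idx[members, members]
        mean(upperTriVals(sub))
    }, numeric(1))
    names(out) <- sort(unique(labels))
    out
}

#' Consensus score
#'
#' Splits the off-diagonal consensus indices at the chance level \eqn{1/K}
#' into an above bin (strictly greater) and a below bin, and reports the
#' difference of the two bin means,
#' \eqn{CS = \overline{ci}_{above} - \overline{ci}_{below}}.  Near 0 when
#' indices scatter around chance (no consensus), 1 when every index is 0 or
#' 1 (perfect consensus).  An empty bin contributes 0.
#'
#' @param M a [ConsensusMatrix-class].
#' @return the consensus score, a scalar.
#' @examples
#' # indices {0.9, 0.8, 0.1} at K = 2: above = 0.85, below = 0.1, CS = 0.75
#' @export
consensusScore <- function(M) {
    vals <- upperTriVals(consensusIndices(M))
    chance <- 1 / M@K
    above <- vals[vals > chance]
    below <- vals[vals <= chance]
    (if (length(above)) mean(above) else 0) -
        (if (length(below)) mean(below) else 0)
}

#' Final cluster labels from the consensus matrix
#'
#' K-means on the rows of the consensus matrix: each variable is
#' represented by its consensus profile, so variables that co-cluster
#' consistently share nearly identical profiles and fall into the same
#' final cluster.
#'
#' @param M a [ConsensusMatrix-class].
#' @param K number of clusters (default: the K the matrix was built with).
#' @param seed integer RNG seed.
#' @param nInit K-means restarts (default 10).
#' @return named integer vector of cluster ids, one per variable.
#' @export
finalLabels <- function(M, K = M@K, seed, nInit = 10) {
    idx <- consensusIndices(M)
    if (K > nrow(idx)) stop("more clusters than variables")
    withSeed(seed, safeKmeans(idx, K, nInit)$cluster)
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting agreement corrected for chance under the hypergeometric
#' (fixed cluster sizes) model:
#' \eqn{ARI = (\mathrm{index} - \mathrm{E[index]}) /
#' (\mathrm{max\,index} - \mathrm{E[index]})}.  1 for identical partitions
#' (up to label renaming), about 0 for independent ones.
#'
#' @param a,b equal-length label vectors.
#' @return a scalar, at most 1.
#' @examples
#' adjustedRand(c(1, 1, 2, 2), c(1, 2, 1, 2))  # -0.5
#' @export
adjustedRand <- function(a, b) {
    if (length(a) != length(b)) stop("label vectors differ in length")
    tab <- table(a, b)
    n <- length(a)
    sumij <- sum(choose(tab, 2))
    ea <- sum(choose(rowSums(tab), 2))
    eb <- sum(choose(colSums(tab), 2))
    expected <- ea * eb / choose(n, 2)
    maximum <- (ea + eb) / 2
    if (abs(maximum - expected) < .Machine$double.eps) return(1)
    (sumij - expected) / (maximum - expected)
}

#' Adjusted mutual information between two partitions
#'
#' Mutual information corrected by its expectation under the permutation
#' (hypergeometric) model and normalized by the larger marginal entropy:
#' \eqn{AMI = (MI - E[MI]) / (\max(H_a, H_b) - E[MI])}.  1 for identical
#' partitions, about 0 for independent ones; 0 when either partition
#' carries no information (single cluster).
#'
#' @param a,b equal-length label vectors.
#' @return a scalar, at most 1 (up to floating point).
#' @export
adjustedMutualInfo <- function(a, b) {
    if (length(a) != length(b)) stop("label vectors differ in length")
    tab <- table(a, b)
    n <- length(a)
    ai <- rowSums(tab)
    bj <- colSums(tab)
    Ha <- -sum((ai / n) * log(ai / n))
    Hb <- -sum((bj / n) * log(bj / n))
    pij <- tab / n
    nz <- tab > 0
    mi <- sum(pij[nz] * log(pij[nz] / (outer(ai, bj) / n^2)[nz]))
    # expected MI under random permutations with fixed marginals
    emi <- 0
    for (i in seq_along(ai)) {
        for (j in seq_along(bj)) {
            lo <- max(1, ai[i] + bj[j] - n)
            hi <- min(ai[i], bj[j])
            for (nij in lo:hi) {
                logp <- lgamma(ai[i] + 1) + lgamma(bj[j] + 1) +
                    lgamma(n - ai[i] + 1) + lgamma(n - bj[j] + 1) -
                    lgamma(n + 1) - lgamma(nij + 1) -
                    lgamma(ai[i] - nij + 1) - lgamma(bj[j] - nij + 1) -
                    lgamma(n - ai[i] - bj[j] + nij + 1)
                emi <- emi + exp(logp) * (nij / n) *
                    log(n * nij / (ai[i] * bj[j]))
            }
        }
    }
    denom <- max(Ha, Hb) - emi
    if (abs(denom) < 1e-14) return(0)
    as.numeric((mi - emi) / denom)
}

#' Write consensus artifacts
#'
#' Writes the consensus matrix as labeled CSV, per-K diagnostics as JSON,
#' and final labels as a two-column CSV.
#'
#' @param M a [ConsensusMatrix-class].
#' @param labels optional final labels for [clusterConsensus()] output.
#' @param prefix file path prefix.
#' @export
writeConsensus <- function(M, prefix, labels = NULL) {
    utils::write.csv(data.frame(variable = rownames(M@indices),
                                M@indices, check.names = FALSE),
                     paste0(prefix, "_matrix.csv"), row.names = FALSE)
    dg <- consensusCdfAuc(M)
    info <- list(K = M@K, nIterations = M@nIterations,
                 fraction = M@fraction, auc = dg$auc,
                 consensusScore = consensusScore(M))
    if (!is.null(labels)) {
        info$clusterConsensus <- as.list(clusterConsensus(M, labels))
        utils::write.csv(data.frame(variable = names(labels),
                                    cluster = as.integer(labels)),
                         paste0(prefix, "_labels.csv"), row.names = FALSE)
    }
    jsonlite::write_json(info, paste0(prefix, "_diagnostics.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(prefix)
}
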