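# Hungarian algorithm (shortest augmenting path, O(n^3)) for the square
# assignment problem.  Returns, for each row, the column it is assigned to
# in the minimum-total-cost perfect matching.
hungarianAssign <- function(cost) {
    cost <- as.matrix(cost)
    n <- nrow(cost)
    if (ncol(cost) != n) stop("cost matrix must be square")
    if (n == 1L) return(1L)
    # potentials / matching use index 1 for the virtual 0th row/column
    u <- numeric(n + 1L)
    v <- numeric(n + 1L)
    p <- integer(n + 1L)        # p[j+1]: row matched to column j (0 = free)
    for (i in seq_len(n)) {
        p[1L] <- i
        j0 <- 0L
        minv <- rep(Inf, n)
        way <- integer(n)
        used <- rep(FALSE, n + 1L)
        repeat {
            used[j0 + 1L] <- TRUE
            i0 <- p[j0 + 1L]
            delta <- Inf
            j1 <- 0L
            for (j in seq_len(n)) {
                if (!used[j + 1L]) {
                    cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
                    if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
                    if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
                }
            }
            for (j in 0L:n) {
                if (used[j + 1L]) {
                    u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
                    v[j + 1L] <- v[j + 1L] - delta
                } else {
                    minv[j] <- minv[j] - delta
                }
            }
            j0 <- j1
            if (p[j0 + 1L] == 0L) break
        }
        repeat {
            j1 <- way[j0]
            p[j0 + 1L] <- p[j1 + 1L]
            j0 <- j1
            if (j0 == 0L) break
        }
    }
    ans <- integer(n)
    for (j in seq_len(n)) if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
    ans
}

#' Match factors between two solutions by the Hungarian algorithm
#'
#' Finds the factor pairing that minimizes the total cost
#' \eqn{\sum_f (1 - |r_f|)}, where \eqn{r_f} is the Pearson correlation
#' between matched loading vectors, and picks signs so matched correlations
#' are nonnegative.  Degenerate (zero-variance) loading columns get
#' correlation 0.
#'
#' @param reference,other variables x k loading matrices over the same
#'   variables with equal factor counts.
#' @return list with `permutation` (column of `other` matched to each
#'   reference factor), `signs` (+1/-1 per reference factor), and
#'   `correlations` (matched absolute correlations).
#' @export
matchFactors <- function(reference, other) {
    reference <- as.matrix(reference)
    other <- as.matrix(other)
    if (!all(dim(reference) == dim(other)))
        stop("loading matrices must have identical dimensions")
    C <- suppressWarnings(stats::cor(reference, other))
    C[!is.finite(C)] <- 0
    perm <- hungarianAssign(1 - abs(C))
    matched <- C[cbind(seq_len(ncol(C)), perm)]
    signs <- ifelse(matched < 0, -1, 1)
    list(permutation = perm, signs = signs, correlations = abs(matched))
}

#' Parallel analysis for the candidate number of factors
#'
#' Compares per-factor shared variance in the data against the average over
#' `nReps` pure-noise matrices of identical dimensions (i.i.d. standard
#' normal).  The crossover — the number of leading factors whose real value
#' still exceeds the null mean — bounds the dimensionalities worth
#' examining.  By default the shared-variance measure is the correlation
#' eigenvalue spectrum; `method = "ml"` instead fits the ML factor model
#' with `kMax` factors and uses per-factor sums of squared loadings.
#'
#' @param data subjects x variables standardized matrix.
#' @param nReps number of synthetic repetitions (default 20).
#' @param seed integer RNG seed.
#' @param method `"eigen"` (default) or `"ml"`.
#' @param kMax factors to extract under `method = "ml"` (default
#'   `floor(ncol(data)/2)`).
#' @return a `ParallelAnalysisResult` list: `realValues`, `nullMeans`,
#'   `nReps`, `crossover`, `method`.
#' @export
parallelAnalysis <- function(data, nReps = 20, seed,
                             method = c("eigen", "ml"), kMax = NULL) {
    method <- match.arg(method)
    if (nReps < 2) stop("'nReps' must be at least 2")
    n <- nrow(data)
    p <- ncol(data)
    sharedVariance <- function(x) {
        if (method == "eigen") eigen(stats::cor(x), symmetric = TRUE,
                                     only.values = TRUE)$values
        else explainedVariance(fitMlFactors(stats::cor(x), kMax,
                                            nObs = nrow(x)))
    }
    if (method == "ml" && is.null(kMax)) kMax <- max(1L, floor(p / 2))
    real <- sharedVariance(data)
    nulls <- vapply(seq_len(nReps), function(r)
        sharedVariance(generateNullMatrix(n, p, seed = seed + r - 1L)),
        numeric(length(real)))
    nullMeans <- rowMeans(nulls)
    below <- which(real <= nullMeans)
    crossover <- if (length(below)) below[1L] - 1L else length(real)
    structure(list(realValues = real, nullMeans = nullMeans,
                   nReps = as.integer(nReps),
                   crossover = as.integer(crossover), method = method),
              class = "ParallelAnalysisResult")
}

#' @export
print.ParallelAnalysisResult <- function(x, ...) {
    cat("Parallel analysis (", x$method, ", ", x$nReps, " reps): crossover at ",
        x$crossover, " factor(s)\n", sep = "")
    k <- min(length(x$realValues), x$crossover + 3L)
    print(round(rbind(real = x$realValues[seq_len(k)],
                      null = x$nullMeans[seq_len(k)]), 3))
    invisible(x)
}

#' Factor robustness under subject subsampling
#'
#' For each of `nIter` iterations, a fraction of subjects is drawn without
#' replacement, factors are extracted and rotated for every candidate
#' dimensionality, and each subsample's factors are aligned to the
#' full-data solution at the same `k` via [matchFactors()].  Per (k,
#' factor) the mean absolute pairwise correlation of the aligned loading
#' vectors over all subsample pairs measures how stably that factor is
#' recovered.
#'
#' @param data subjects x variables standardized matrix.
#' @param kMax largest number of factors to examine.
#' @param nIter number of subsamples (default 1000).
#' @param fraction subject fraction per subsample (default 0.8).
#' @param seed integer RNG seed.
#' @param kValues candidate dimensionalities (default `1:kMax`).
#' @return a `RobustnessResult` list: `meanAbsCor` (kMax x kMax matrix,
#'   `NA` above the diagonal), `nIter`, `fraction`.
#' @export
robustnessSubsampling <- function(data, kMax, nIter = 1000, fraction = 0.8,
                                  seed, kValues = seq_len(kMax)) {
    if (fraction <= 0 || fraction > 1) stop("'fraction' must be in (0, 1]")
    if (kMax < 1) stop("'kMax' must be at least 1")
    n <- nrow(data)
    V <- ncol(data)
    m <- max(2L, round(fraction * n))
    refs <- lapply(kValues, function(k) loadings(efa(data, k)))
    names(refs) <- kValues
    store <- lapply(kValues, function(k) array(NA_real_, c(V, k, nIter)))
    names(store) <- kValues
    withSeed(seed, {
        for (it in seq_len(nIter)) {
            idx <- sample(n, m)
            for (ki in seq_along(kValues)) {
                k <- kValues[ki]
                if (m <= k + 1L) {
                    warning("subsample too small for k = ", k,
                            "; iteration skipped")
                    next
                }
                sol <- tryCatch(suppressWarnings(
                    efa(data[idx, , drop = FALSE], k)),
                    error = function(e) NULL)
                if (is.null(sol)) next
                mt <- matchFactors(refs[[ki]], loadings(sol))
                aligned <- loadings(sol)[, mt$permutation, drop = FALSE]
                aligned <- aligned * rep(mt$signs, each = V)
                store[[ki]][, , it] <- aligned
            }
        }
    })
    out <- matrix(NA_real_, length(kValues), max(kValues),
                  dimnames = list(paste0("k", kValues),
                                  paste0("F", seq_len(max(kValues)))))
    for (ki in seq_along(kValues)) {
        k <- kValues[ki]
        for (f in seq_len(k)) {
            vecs <- store[[ki]][, f, ]
            ok <- !apply(is.na(vecs), 2L, any)
            cc <- suppressWarnings(stats::cor(vecs[, ok, drop = FALSE]))
            cc[!is.finite(cc)] <- 0
            out[ki, f] <- mean(abs(upperTriVals(cc)))
        }
    }
    structure(list(meanAbsCor = out, nIter = as.integer(nIter),
                   fraction = fraction, kValues = kValues),
              class = "RobustnessResult")
}

#' @export
print.RobustnessResult <- function(x, ...) {
    cat("Factor robustness over", x$nIter, "subsamples of",
        sprintf("%.0f%%", 100 * x$fraction), "of subjects\n")
    print(round(x$meanAbsCor, 3))
    invisible(x)
}

#' Interpretability rule: salient loadings per factor
#'
#' A factor is considered interpretable when at least `minVariables`
#' variables load on it with absolute loadings above `threshold`.
#'
#' @param sol a [FactorSolution-class] (or loading matrix).
#' @param threshold salience cutoff (default 0.4).
#' @param minVariables required salient variables per factor (default 3).
#' @return data frame with per-factor `count` and `pass`.
#' @export
interpretabilityCounts <- function(sol, threshold = 0.4, minVariables = 3) {
    L <- if (is(sol, "FactorSolution")) loadings(sol) else as.matrix(sol)
    counts <- colSums(abs(L) > threshold)
    data.frame(factor = colnames(L) %||% paste0("F", seq_along(counts)),
               count = as.integer(counts), pass = counts >= minVariables)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Correlate factor loadings between two solutions
#'
#' All-pairs Pearson correlations between the loading vectors of two
#' solutions over the same variables, plus (for equal factor counts) the
#' matched diagonal after Hungarian alignment — the standard way to
#' quantify how well factors replicate across datasets.
#'
#' @param solA,solB [FactorSolution-class] objects over identical variables.
#' @return list with `correlations` (kA x kB matrix), and for equal factor
#'   counts `matchedDiagonal` and `permutation` from [matchFactors()].
#' @export
compareSolutions <- function(solA, solB) {
    LA <- loadings(solA)
    LB <- loadings(solB)
    if (!identical(rownames(LA), rownames(LB)))
        stop("solutions must cover the same variables, in the same order")
    R <- stats::cor(LA, LB)
    out <- list(correlations = R)
    if (ncol(LA) == ncol(LB)) {
        mt <- matchFactors(LA, LB)
        out$matchedDiagonal <- mt$correlations
        out$permutation <- mt$permutation
    }
    out
}

#' Assemble the dimensionality-selection report
#'
#' Evaluates every candidate dimensionality on the three selection
#' criteria: model fit (percent of total variance explained, which should
#' be as high as the other criteria allow), interpretability (every factor
#' has at least `minVariables` loadings above `loadingThreshold`), and
#' robustness (every factor's subsample stability above
#' `robustnessThreshold`).  A `k` is flagged when it passes both threshold
#' criteria; the final choice remains the analyst's.
#'
#' @param data subjects x variables standardized matrix.
#' @param kMax largest dimensionality to evaluate (e.g. the parallel
#'   analysis crossover).
#' @param nIter,fraction subsampling settings passed to
#'   [robustnessSubsampling()].
#' @param seed integer RNG seed.
#' @param loadingThreshold,minVariables interpretability rule (defaults
#'   0.4 / 3).
#' @param robustnessThreshold minimum per-factor mean |r| (default 0.9).
#' @return a `DimensionalityReport`: data frame with one row per `k`
#'   (`percentVariance`, `deltaPercentVariance`, `interpretable`,
#'   `minRobustness`, `flagged`), with attributes `recommended` (largest
#'   flagged `k`) and `robustness`.
#' @export
evaluateDimensionality <- function(data, kMax, nIter = 100, fraction = 0.8,
                                   seed, loadingThreshold = 0.4,
                                   minVariables = 3,
                                   robustnessThreshold = 0.9) {
    rob <- robustnessSubsampling(data, kMax, nIter = nIter,
                                 fraction = fraction, seed = seed)
    rows <- lapply(seq_len(kMax), function(k) {
        sol <- efa(data, k)
        pv <- sum(explainedVariance(sol, percent = TRUE))
        interp <- all(interpretabilityCounts(sol, loadingThreshold,
                                             minVariables)$pass)
        minRob <- min(rob$meanAbsCor[k, seq_len(k)])
        data.frame(k = k, percentVariance = pv, interpretable = interp,
                   minRobustness = minRob,
                   flagged = interp && minRob > robustnessThreshold)
    })
    rep <- do.call(rbind, rows)
    rep$deltaPercentVariance <- c(rep$percentVariance[1L],
                                  diff(rep$percentVariance))
    rep <- rep[, c("k", "percentVariance", "deltaPercentVariance",
                   "interpretable", "minRobustness", "flagged")]
    attr(rep, "recommended") <-
        if (any(rep$flagged)) max(rep$k[rep$flagged]) else NA_integer_
    attr(rep, "robustness") <- rob
    class(rep) <- c("DimensionalityReport", "data.frame")
    rep
}

#' @export
print.DimensionalityReport <- function(x, ...) {
    cat("Dimensionality report (recommended k =",
        attr(x, "recommended"), ")\n")
    print.data.frame(x, digits = 3, row.names = FALSE)
    invisible(x)
}
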