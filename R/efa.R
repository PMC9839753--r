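#' Maximum-likelihood factor extraction
#'
#' Fits the orthogonal common-factor model \eqn{\Sigma = L L' + U^2} to a
#' correlation matrix by minimizing the maximum-likelihood discrepancy
#' \deqn{E = \tfrac{1}{2}\,\mathrm{tr}\big(((S - \Sigma)\Sigma^{-1})^2\big).}
#' The fit is parameterized by the uniquenesses: for a trial \eqn{U^2} the
#' conditionally optimal loadings come from the leading eigenpairs of
#' \eqn{U^{-1} S U^{-1}} (the standard ML-FA device), and the uniquenesses
#' are optimized by quasi-Newton descent on the log scale.  Uniquenesses are
#' floored at `psiFloor` to guard against Heywood cases (a warning is
#' emitted when the floor binds).
#'
#' @param S symmetric positive semi-definite correlation matrix.
#' @param k number of factors, `1 <= k < ncol(S)`.
#' @param nObs number of observations behind `S`.
#' @param psiFloor lower bound for uniquenesses (default 0.005).
#' @param maxit optimizer iteration cap.
#' @return an unrotated [FactorSolution-class], factors ordered by
#'   decreasing explained variance, each signed so its largest-magnitude
#'   loading is positive.
#' @examples
#' sol <- fitMlFactors(diag(5), k = 1, nObs = 100)
#' max(abs(loadings(sol)))   # ~0: no shared variance in the identity
#' @export
fitMlFactors <- function(S, k, nObs, psiFloor = 0.005, maxit = 500) {
    S <- as.matrix(S)
    p <- ncol(S)
    if (k < 1 || k >= p) stop("'k' must satisfy 1 <= k < ncol(S)")
    if (max(abs(S - t(S))) > 1e-8) stop("'S' must be symmetric")
    if (any(abs(diag(S) - 1) > 1e-6)) S <- stats::cov2cor(S)
    vnames <- colnames(S)
    if (is.null(vnames)) vnames <- paste0("v", seq_len(p))

    loadFromPsi <- function(psi) {
        sc <- 1 / sqrt(psi)
        A <- S * outer(sc, sc)
        e <- eigen(A, symmetric = TRUE)
        lam <- pmax(e$values[seq_len(k)] - 1, 0)
        L <- e$vectors[, seq_len(k), drop = FALSE] *
            rep(sqrt(lam), each = p)
        L * sqrt(psi)
    }
    discrepancyOf <- function(L, psi) {
        Sigma <- tcrossprod(L) + diag(psi, p)
        B <- (S - Sigma) %*% solve(Sigma)
        0.5 * sum(B * t(B))
    }

    # Stage 1: profile likelihood over the uniquenesses.  For fixed psi the
    # conditionally optimal loadings come from the leading eigenpairs of
    # U^-1 S U^-1; the profiled deviance reduces to a sum over the trailing
    # eigenvalues, with a closed-form gradient.
    profileFn <- function(logpsi) {
        psi <- exp(logpsi)
        sc <- 1 / sqrt(psi)
        e <- eigen(S * outer(sc, sc), symmetric = TRUE,
                   only.values = TRUE)$values
        tail <- e[-seq_len(k)]
        sum(tail - log(pmax(tail, 1e-12)) - 1)
    }
    profileGr <- function(logpsi) {
        psi <- exp(logpsi)
        L <- loadFromPsi(psi)
        g <- rowSums(L^2) + psi - diag(S)
        (g / psi^2) * psi          # chain rule through psi = exp(logpsi)
    }
    start <- (1 - 0.5 * k / p) / diag(solve(S))
    start <- pmin(pmax(start, 2 * psiFloor), 1)
    opt1 <- stats::optim(log(start), profileFn, profileGr,
                         method = "L-BFGS-B", lower = log(psiFloor),
                         upper = log(10), control = list(maxit = maxit))
    psi <- exp(opt1$par)
    L <- loadFromPsi(psi)

    # Stage 2: polish loadings and uniquenesses jointly on the trace
    # discrepancy itself, with its analytic gradient.
    jointFn <- function(par) {
        L <- matrix(par[seq_len(p * k)], p, k)
        psi <- exp(par[p * k + seq_len(p)])
        discrepancyOf(L, psi)
    }
    jointGr <- function(par) {
        L <- matrix(par[seq_len(p * k)], p, k)
        psi <- exp(par[p * k + seq_len(p)])
        Sigma <- tcrossprod(L) + diag(psi, p)
        Sinv <- solve(Sigma)
        M <- S - Sigma
        G <- -(Sinv %*% M %*% Sinv + Sinv %*% M %*% Sinv %*% M %*% Sinv)
        c(2 * G %*% L, diag(G) * psi)
    }
    opt <- stats::optim(c(L, log(psi)), jointFn, jointGr,
                        method = "L-BFGS-B",
                        lower = c(rep(-Inf, p * k), rep(log(psiFloor), p)),
                        upper = c(rep(Inf, p * k), rep(log(10), p)),
                        control = list(maxit = maxit, factr = 1e4))
    converged <- opt$convergence == 0L || opt$convergence == 1L
    if (!converged)
        warning("ML factor extraction did not converge (k = ", k, "): ",
                opt$message)
    psi <- exp(opt$par[p * k + seq_len(p)])
    if (any(psi <= psiFloor * 1.001))
        warning("Heywood guard active: ", sum(psi <= psiFloor * 1.001),
                " uniqueness(es) at the floor of ", psiFloor)
    L <- matrix(opt$par[seq_len(p * k)], p, k)
    # Identifiability convention: a factor carried by a single variable is
    # indistinguishable from that variable's uniqueness (l^2 + psi is the
    # only identified quantity), so its variance is folded back into psi.
    for (f in seq_len(k)) {
        nz <- abs(L[, f]) > 1e-4
        if (sum(nz) == 1L) {
            v <- which(nz)
            psi[v] <- psi[v] + L[v, f]^2
            L[v, f] <- 0
        }
    }
    L <- orderAndSign(L)
    rownames(L) <- vnames
    names(psi) <- vnames
    new("FactorSolution", loadings = L, uniquenesses = psi,
        explainedVariance = colSums(L^2), nFactors = as.integer(k),
        rotated = FALSE, converged = converged, nObs = as.integer(nObs),
        discrepancy = opt$value)
}

#' Varimax rotation of a loading matrix
#'
#' Orthogonal rotation maximizing the varimax criterion (the summed
#' per-factor variance of squared loadings), driving the solution toward
#' simple structure.  Row communalities are invariant.  Kaiser row
#' normalization is off by default.
#'
#' @param L variables x factors loading matrix; returned unchanged when
#'   `ncol(L) < 2`.
#' @param kaiser apply Kaiser row normalization during rotation.
#' @return the rotated loading matrix (same dimnames).
#' @export
varimaxRotate <- function(L, kaiser = FALSE) {
    L <- as.matrix(L)
    if (ncol(L) < 2L) return(L)
    rot <- stats::varimax(L, normalize = kaiser, eps = 1e-10)
    out <- L %*% rot$rotmat
    dimnames(out) <- dimnames(L)
    out
}

#' Rotate a factor solution
#'
#' Applies [varimaxRotate()] to a fitted solution, then re-orders factors by
#' explained variance and fixes signs.  Uniquenesses, communalities and the
#' reconstructed covariance are unchanged by the rotation.
#'
#' @param sol a [FactorSolution-class].
#' @param kaiser passed to [varimaxRotate()].
#' @return the rotated [FactorSolution-class] (`rotated = TRUE`).
#' @export
rotateSolution <- function(sol, kaiser = FALSE) {
    L <- orderAndSign(varimaxRotate(loadings(sol), kaiser = kaiser))
    rownames(L) <- rownames(loadings(sol))
    initialize(sol, loadings = L, explainedVariance = colSums(L^2),
               rotated = TRUE)
}

#' One-stop exploratory factor analysis
#'
#' Correlates the standardized data, extracts `k` maximum-likelihood
#' factors and (for `k >= 2`, by default) varimax-rotates them.
#'
#' @param data subjects x variables standardized numeric matrix.
#' @param k number of factors.
#' @param rotate apply varimax rotation (default `TRUE`).
#' @param ... passed to [fitMlFactors()].
#' @return a [FactorSolution-class].
#' @export
efa <- function(data, k, rotate = TRUE, ...) {
    sol <- fitMlFactors(stats::cor(data), k, nObs = nrow(data), ...)
    if (rotate && k >= 2) rotateSolution(sol) else sol
}

#' Reconstruct the model-implied covariance
#'
#' @param sol a [FactorSolution-class].
#' @return \eqn{\Sigma = L L' + U^2}, a symmetric matrix with (near-)unit
#'   diagonal on standardized input.
#' @export
reconstructCovariance <- function(sol) {
    tcrossprod(loadings(sol)) + diag(uniquenesses(sol),
                                     nrow(loadings(sol)))
}

#' Maximum-likelihood discrepancy between two covariance matrices
#'
#' Evaluates \eqn{E = \tfrac{1}{2}\mathrm{tr}(((S - \Sigma)\Sigma^{-1})^2)},
#' the objective the ML factor extraction minimizes.  Nonnegative, and zero
#' exactly when \eqn{S = \Sigma}.
#'
#' @param S sample covariance matrix.
#' @param Sigma model-implied covariance matrix; must be invertible.
#' @return a nonnegative scalar.
#' @examples
#' mlDiscrepancy(diag(c(2, 1)), diag(2))  # 0.5
#' @export
mlDiscrepancy <- function(S, Sigma) {
    Sinv <- tryCatch(solve(Sigma),
                     error = function(e) stop("'Sigma' is singular"))
    B <- (S - Sigma) %*% Sinv
    0.5 * sum(B * t(B))
}

#' Bartlett factor scores
#'
#' Weighted least-squares estimates of subject positions on the latent
#' factors: \eqn{\hat F = X\, U^{-2} L (L' U^{-2} L)^{-1}}, the univocal and
#' conditionally unbiased estimator.
#'
#' @param data subjects x variables standardized matrix whose columns match
#'   the solution's variables.
#' @param sol a [FactorSolution-class] with strictly positive uniquenesses.
#' @return subjects x factors score matrix with attribute `method =
#'   "Bartlett"`.
#' @export
bartlettScores <- function(data, sol) {
    L <- loadings(sol)
    psi <- uniquenesses(sol)
    if (ncol(data) != nrow(L))
        stop("'data' columns must match the solution's variables")
    if (!is.null(colnames(data)) && !is.null(rownames(L)) &&
        !identical(colnames(data), rownames(L)))
        stop("variable names of 'data' and the solution disagree")
    if (any(psi <= 0)) stop("uniquenesses must be strictly positive")
    Lw <- L / psi                       # U^-2 L (rows scaled by 1/psi_v)
    M <- crossprod(L, Lw)               # L' U^-2 L
    W <- tryCatch(Lw %*% solve(M),
                  error = function(e) stop("L' U^-2 L is singular"))
    scores <- as.matrix(data) %*% W
    colnames(scores) <- colnames(L)
    attr(scores, "method") <- "Bartlett"
    scores
}

#' @describeIn FactorSolution-class compact display.
#' @param object a `FactorSolution`.
#' @export
setMethod("show", "FactorSolution", function(object) {
    p <- nrow(object@loadings)
    cat("FactorSolution: ", object@nFactors, " factor(s), ", p,
        " variables (n = ", object@nObs, ")\n", sep = "")
    cat("  ", if (object@rotated) "varimax-rotated" else "unrotated",
        if (object@converged) ", converged" else ", NOT converged",
        " | discrepancy = ", format(object@discrepancy, digits = 4),
        "\n", sep = "")
    pv <- 100 * object@explainedVariance / p
    cat("  % variance:", paste(sprintf("%.1f", pv), collapse = ", "),
        sprintf("(total %.1f%%)\n", sum(pv)))
})

#' Write a factor solution as CSV + JSON
#'
#' Writes `<prefix>_loadings.csv` (variables x factors, with uniquenesses)
#' and `<prefix>_meta.json` (fit metadata and explained variance).
#'
#' @param sol a [FactorSolution-class].
#' @param prefix file path prefix.
#' @export
writeFactorSolution <- function(sol, prefix) {
    L <- loadings(sol)
    df <- data.frame(variable = rownames(L), L,
                     uniqueness = uniquenesses(sol), check.names = FALSE)
    utils::write.csv(df, paste0(prefix, "_loadings.csv"), row.names = FALSE)
    jsonlite::write_json(
        list(nFactors = sol@nFactors, rotated = sol@rotated,
             converged = sol@converged, nObs = sol@nObs,
             discrepancy = sol@discrepancy,
             explainedVariance = sol@explainedVariance,
             percentVariance = 100 * sol@explainedVariance / nrow(L)),
        paste0(prefix, "_meta.json"), auto_unbox = TRUE, digits = NA)
    invisible(prefix)
}
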