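#' Derive a CFA loading pattern from an EFA solution
#'
#' Variables with absolute rotated loadings above `threshold` become the
#' indicator variables of the corresponding factor (their loadings are
#' estimated freely); all other loadings are fixed to 0.  Variables with no
#' loading above the threshold are excluded from the CFA variable set.
#' Factor variances are fixed to 1 in the resulting model; factor
#' covariances are free unless `factorCovFree = FALSE`.
#'
#' @param sol a rotated [FactorSolution-class].
#' @param threshold indicator cutoff on absolute loadings (default 0.45).
#' @param factorCovFree estimate factor covariances (default `TRUE`).
#' @return a [CfaPattern-class]; a warning is issued for factors left with
#'   fewer than 2 indicators (possible under-identification).
#' @export
patternFromEfa <- function(sol, threshold = 0.45, factorCovFree = TRUE) {
    L <- loadings(sol)
    mask <- abs(L) > threshold
    keep <- rowSums(mask) > 0
    dropped <- rownames(L)[!keep]
    if (length(dropped))
        message(length(dropped), " variable(s) without a salient loading ",
                "excluded from the CFA set")
    mask <- mask[keep, , drop = FALSE]
    if (any(colSums(mask) == 0))
        stop("factor(s) without any indicator at threshold ", threshold)
    if (any(colSums(mask) < 2))
        warning("factor(s) with fewer than 2 indicators; ",
                "the model may be under-identified")
    new("CfaPattern", freeMask = mask, factorCovFree = factorCovFree,
        startLoadings = L[keep, , drop = FALSE] * mask,
        dropped = as.character(dropped))
}

#' Fit a confirmatory factor model by maximum likelihood
#'
#' Minimizes the ML discrepancy
#' \deqn{F_{ML} = \mathrm{tr}(S\Sigma^{-1}) - \ln|S\Sigma^{-1}| - p}
#' over the free parameters of \eqn{\Sigma = \Lambda\Phi\Lambda' + \Theta}
#' (loadings free where the pattern allows, \eqn{\Phi} with unit diagonal
#' and free or zero off-diagonals, \eqn{\Theta} diagonal and free), using
#' analytic gradients.  The model chi-square is
#' \eqn{(n - 1)\,F_{ML}} at the optimum; the independence baseline and all
#' fit indices are filled in via [baselineModel()] and [fitIndices()].
#'
#' @param S covariance (typically correlation) matrix over at least the
#'   pattern's variables; the data are assumed z-scored upstream.
#' @param pattern a [CfaPattern-class].
#' @param nObs number of observations behind `S`.
#' @param chiSquareMultiplier `"n-1"` (default) or `"n"`.
#' @return a [CfaFit-class] with estimates, chi-square, df, baseline,
#'   CFI, TLI, RMSEA (+90% CI) and SRMR.  Non-convergence is reported via
#'   the `converged` slot, not an error.
#' @export
fitCfa <- function(S, pattern, nObs,
                   chiSquareMultiplier = c("n-1", "n")) {
    chiSquareMultiplier <- match.arg(chiSquareMultiplier)
    mask <- pattern@freeMask
    vars <- rownames(mask)
    if (!all(vars %in% colnames(S)))
        stop("'S' does not cover the pattern's variables")
    S <- S[vars, vars]
    p <- length(vars)
    k <- ncol(mask)
    covFree <- isTRUE(pattern@factorCovFree) && k >= 2
    nPhi <- if (covFree) k * (k - 1L) / 2L else 0L
    nFree <- sum(mask) + p + nPhi
    df <- as.integer(p * (p + 1L) / 2L - nFree)
    lowPhi <- if (covFree) rep(-0.995, nPhi) else numeric(0)

    unpack <- function(par) {
        lam <- matrix(0, p, k, dimnames = dimnames(mask))
        lam[mask] <- par[seq_len(sum(mask))]
        phi <- diag(k)
        if (covFree)
            phi[upper.tri(phi)] <- par[sum(mask) + seq_len(nPhi)]
        phi[lower.tri(phi)] <- t(phi)[lower.tri(phi)]
        theta <- exp(par[(nFree - p + 1L):nFree])
        list(lam = lam, phi = phi, theta = theta)
    }
    impliedOf <- function(q) q$lam %*% q$phi %*% t(q$lam) + diag(q$theta, p)
    ldS <- determinant(S)$modulus
    fml <- function(par) {
        q <- unpack(par)
        Sigma <- impliedOf(q)
        ch <- tryCatch(chol(Sigma), error = function(e) NULL)
        if (is.null(ch)) return(1e8 + sum(par^2))
        ldSig <- 2 * sum(log(diag(ch)))
        Sinv <- chol2inv(ch)
        as.numeric(sum(S * Sinv) + ldSig - ldS - p)
    }
    grad <- function(par) {
        q <- unpack(par)
        Sigma <- impliedOf(q)
        ch <- tryCatch(chol(Sigma), error = function(e) NULL)
        if (is.null(ch)) return(2 * par)
        Sinv <- chol2inv(ch)
        G <- Sinv %*% (Sigma - S) %*% Sinv
        gLam <- 2 * G %*% q$lam %*% q$phi
        gPhi <- t(q$lam) %*% G %*% q$lam
        gTheta <- diag(G) * q$theta
        c(gLam[mask],
          if (covFree) 2 * gPhi[upper.tri(gPhi)] else numeric(0),
          gTheta)
    }

    startLam <- pattern@startLoadings[mask]
    startLam[startLam == 0] <- 0.5
    start <- c(startLam, rep(0, nPhi),
               log(pmax(1 - rowSums(pattern@startLoadings^2), 0.2)))
    opt <- tryCatch(
        stats::optim(start, fml, grad, method = "L-BFGS-B",
                     lower = c(rep(-Inf, sum(mask)), lowPhi,
                               rep(log(1e-4), p)),
                     upper = c(rep(Inf, sum(mask)),
                               if (covFree) rep(0.995, nPhi) else numeric(0),
                               rep(log(10), p)),
                     control = list(maxit = 1000)),
        error = function(e)
            stats::optim(start, fml, method = "Nelder-Mead",
                         control = list(maxit = 5000)))
    converged <- opt$convergence == 0L && opt$value < 1e7
    q <- unpack(opt$par)
    implied <- impliedOf(q)
    mult <- if (chiSquareMultiplier == "n-1") nObs - 1L else nObs
    chisq <- mult * max(opt$value, 0)
    base <- baselineModel(S, nObs, chiSquareMultiplier)
    fit <- new("CfaFit", loadings = q$lam, residualVariances = q$theta,
               factorCov = q$phi, implied = implied, sampleCov = S,
               fml = opt$value, chiSquare = chisq, df = df,
               baselineChiSquare = unname(base["chiSquare"]),
               baselineDf = as.integer(base["df"]),
               cfi = NA_real_, tli = NA_real_, rmsea = NA_real_,
               rmseaCi90 = c(NA_real_, NA_real_), srmr = NA_real_,
               nObs = as.integer(nObs), converged = converged)
    fitIndices(fit)
}

#' Independence baseline model
#'
#' The null model with uncorrelated variables (diagonal \eqn{\Sigma},
#' variances free) has closed-form ML chi-square
#' \eqn{\chi^2_B = (n-1)\,(-\ln|R|)} for the correlation matrix `R`, with
#' \eqn{p(p-1)/2} degrees of freedom.
#'
#' @param S positive definite covariance matrix.
#' @param nObs number of observations.
#' @param chiSquareMultiplier `"n-1"` (default) or `"n"`.
#' @return named vector with `chiSquare` and `df`.
#' @export
baselineModel <- function(S, nObs, chiSquareMultiplier = c("n-1", "n")) {
    chiSquareMultiplier <- match.arg(chiSquareMultiplier)
    R <- stats::cov2cor(as.matrix(S))
    ch <- tryCatch(chol(R), error = function(e)
        stop("'S' is singular; baseline model undefined"))
    ld <- 2 * sum(log(diag(ch)))
    mult <- if (chiSquareMultiplier == "n-1") nObs - 1L else nObs
    p <- ncol(R)
    c(chiSquare = -mult * ld, df = p * (p - 1) / 2)
}

#' Closed-form fit indices from chi-square summaries
#'
#' \describe{
#' \item{CFI}{\eqn{1 - \max(\chi^2_M - df_M, 0) / \max(\chi^2_B - df_B,
#'   \chi^2_M - df_M, 0)}}
#' \item{TLI}{\eqn{(\chi^2_B/df_B - \chi^2_M/df_M) / (\chi^2_B/df_B - 1)},
#'   truncated above at 1}
#' \item{RMSEA}{\eqn{\sqrt{\max(\chi^2_M - df_M, 0) / (df_M (n - 1))}},
#'   the parsimony-corrected noncentrality per degree of freedom; the 90%
#'   interval inverts the noncentral chi-square CDF at 0.95 / 0.05 over
#'   noncentrality values in \eqn{[0, 10\chi^2]}}
#' }
#'
#' @param chiSquare,df model chi-square and degrees of freedom.
#' @param baselineChiSquare,baselineDf independence-model baseline.
#' @param nObs number of observations.
#' @return list with `cfi`, `tli`, `rmsea`, `rmseaCi90` (length-2).
#' @examples
#' v <- fitIndexValues(100, 50, 1000, 60, 101)
#' round(c(v$cfi, v$tli, v$rmsea), 4)  # 0.9468 0.9362 0.1000
#' @export
fitIndexValues <- function(chiSquare, df, baselineChiSquare, baselineDf,
                           nObs) {
    dM <- max(chiSquare - df, 0)
    dB <- max(baselineChiSquare - baselineDf, chiSquare - df, 0)
    cfi <- if (dB > 0) 1 - dM / dB else 1
    rB <- baselineChiSquare / baselineDf
    if (df == 0) {
        tli <- 1
        rmsea <- 0
        ci <- c(0, 0)
        warning("df = 0: RMSEA undefined, reported as 0")
    } else {
        tli <- min((rB - chiSquare / df) / (rB - 1), 1)
        rmsea <- sqrt(dM / (df * (nObs - 1)))
        ncpAt <- function(prob) {
            # largest ncp with P(X <= chiSquare | df, ncp) >= prob
            f <- function(l) stats::pchisq(chiSquare, df, ncp = l) - prob
            if (f(0) < 0) return(0)
            hi <- max(10 * chiSquare, 1)
            if (f(hi) > 0) return(hi)
            stats::uniroot(f, c(0, hi), tol = 1e-8)$root
        }
        ci <- sqrt(c(ncpAt(0.95), ncpAt(0.05)) / (df * (nObs - 1)))
    }
    list(cfi = cfi, tli = tli, rmsea = rmsea, rmseaCi90 = ci)
}

#' Populate the fit indices of a CfaFit
#'
#' Computes CFI, TLI, RMSEA with its 90% interval (see
#' [fitIndexValues()]), and the SRMR — the root mean square of the
#' standardized residuals \eqn{(s_{ij} - \hat\sigma_{ij}) /
#' \sqrt{s_{ii} s_{jj}}} over the \eqn{p(p+1)/2} unique elements.
#'
#' @param fit a [CfaFit-class] with chi-square, baseline and `nObs` set.
#' @return the fit with index slots populated.
#' @export
fitIndices <- function(fit) {
    v <- fitIndexValues(fit@chiSquare, fit@df, fit@baselineChiSquare,
                        fit@baselineDf, fit@nObs)
    sdS <- sqrt(diag(fit@sampleCov))
    res <- (fit@sampleCov - fit@implied) / outer(sdS, sdS)
    srmr <- sqrt(mean(res[lower.tri(res, diag = TRUE)]^2))
    initialize(fit, cfi = v$cfi, tli = v$tli, rmsea = v$rmsea,
               rmseaCi90 = v$rmseaCi90, srmr = srmr)
}

#' @describeIn CfaFit-class fit summary display in the usual reporting
#'   format.
#' @param object a `CfaFit`.
#' @export
setMethod("show", "CfaFit", function(object) {
    cat("CfaFit: ", ncol(object@loadings), " factor(s), ",
        nrow(object@loadings), " indicators (n = ", object@nObs, ")",
        if (!object@converged) " [NOT converged]", "\n", sep = "")
    cat(sprintf("  Chi-Square (df): %.2f (%d)\n", object@chiSquare,
                object@df))
    cat(sprintf("  CFI %.3f | TLI %.3f | RMSEA %.3f (%.3f-%.3f) | SRMR %.3f\n",
                object@cfi, object@tli, object@rmsea, object@rmseaCi90[1],
                object@rmseaCi90[2], object@srmr))
})

#' Write a CFA fit summary as JSON
#'
#' Emits the standard reporting fields (Chi-Square, df, CFI, TLI, RMSEA
#' with CI, SRMR) plus estimates.
#'
#' @param fit a [CfaFit-class].
#' @param path output file.
#' @export
writeCfaFit <- function(fit, path) {
    jsonlite::write_json(list(
        chiSquare = fit@chiSquare, df = fit@df, cfi = fit@cfi,
        tli = fit@tli, rmsea = fit@rmsea,
        rmseaCi90 = fit@rmseaCi90, srmr = fit@srmr,
        converged = fit@converged, nObs = fit@nObs,
        loadings = as.data.frame(fit@loadings),
        residualVariances = fit@residualVariances,
        factorCov = as.data.frame(fit@factorCov)),
        path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
    invisible(path)
}
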