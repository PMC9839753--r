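# A small true CFA model: 3 factors, 4 indicators each, modest
# factor correlations, used for simulation-based checks.
trueCfaModel <- function() {
    Lam <- matrix(0, 12, 3)
    Lam[1:4, 1] <- c(0.8, 0.7, 0.6, 0.7)
    Lam[5:8, 2] <- c(0.75, 0.7, 0.65, 0.6)
    Lam[9:12, 3] <- c(0.7, 0.8, 0.6, 0.65)
    Phi <- matrix(c(1, 0.3, 0.2, 0.3, 1, 0.25, 0.2, 0.25, 1), 3)
    Theta <- 1 - diag(Lam %*% Phi %*% t(Lam))
    list(Lam = Lam, Phi = Phi, Theta = Theta,
         Sigma = Lam %*% Phi %*% t(Lam) + diag(Theta))
}

simulateFromCfa <- function(model, n, seed) {
    set.seed(seed)
    ch <- chol(model$Sigma)
    x <- matrix(rnorm(n * ncol(ch)), n) %*% ch
    colnames(x) <- paste0("v", seq_len(ncol(ch)))
    x
}

patternOf <- function(model, factorCovFree = TRUE) {
    mask <- model$Lam != 0
    rownames(mask) <- paste0("v", seq_len(nrow(mask)))
    colnames(mask) <- paste0("F", seq_len(ncol(mask)))
    start <- model$Lam
    dimnames(start) <- dimnames(mask)
    new("CfaPattern", freeMask = mask, factorCovFree = factorCovFree,
        startLoadings = start, dropped = character(0))
}

test_that("EFA-derived patterns apply the indicator threshold exactly", {
    L <- cbind(F1 = c(0.80, 0.46, 0.44, 0.05, 0.10, 0.46),
               F2 = c(0.05, 0.10, 0.10, 0.70, 0.46, 0.00))
    rownames(L) <- paste0("v", 1:6)
    sol <- new("FactorSolution", loadings = L,
               uniquenesses = pmax(1 - rowSums(L^2), 0.01),
               explainedVariance = colSums(L^2), nFactors = 2L,
               rotated = TRUE, converged = TRUE, nObs = 100L,
               discrepancy = 0)
    expect_message(pat <- patternFromEfa(sol), "excluded")
    # 0.44 fixed to zero, 0.46 free; v3 has no salient loading
    expect_identical(pat@dropped, "v3")
    expect_equal(unname(rowSums(pat@freeMask)), rep(1, 5))
    expect_true(pat@freeMask["v2", "F1"])
    expect_false(pat@freeMask["v5", "F1"])
    # free-parameter count: 5 loadings + 5 residuals + 1 covariance
    S <- diag(5) + 0.3 - diag(0.3, 5)
    dimnames(S) <- list(rownames(pat@freeMask), rownames(pat@freeMask))
    fit <- fitCfa(S, pat, nObs = 200)
    expect_identical(fit@df, as.integer(5 * 6 / 2 - (5 + 5 + 1)))
})

test_that("degrees of freedom match hand counts", {
    # p = 6, 2 factors, 6 free loadings, 6 residuals, 1 factor covariance
    mask <- matrix(FALSE, 6, 2,
                   dimnames = list(paste0("v", 1:6), c("F1", "F2")))
    mask[1:3, 1] <- TRUE
    mask[4:6, 2] <- TRUE
    start <- matrix(0.6 * mask, 6, 2, dimnames = dimnames(mask))
    pat <- new("CfaPattern", freeMask = mask, factorCovFree = TRUE,
               startLoadings = start, dropped = character(0))
    m <- trueCfaModel()
    S <- m$Sigma[1:6, 1:6]
    dimnames(S) <- list(paste0("v", 1:6), paste0("v", 1:6))
    fit <- fitCfa(S, pat, nObs = 500)
    expect_identical(fit@df, 8L)          # 21 - 13
    # orthogonal variant gains one df
    pat2 <- new("CfaPattern", freeMask = mask, factorCovFree = FALSE,
                startLoadings = start, dropped = character(0))
    expect_identical(fitCfa(S, pat2, nObs = 500)@df, 9L)
})

test_that("fitting the generating model recovers its parameters", {
    m <- trueCfaModel()
    x <- simulateFromCfa(m, 4000, seed = 51)
    fit <- fitCfa(cor(x), patternOf(m), nObs = 4000)
    expect_true(fit@converged)
    expect_lt(fit@fml, 0.02)
    free <- patternOf(m)@freeMask
    expect_lt(max(abs(loadings(fit)[free] - m$Lam[free])), 0.05)
    expect_lt(max(abs(fit@factorCov - m$Phi)), 0.06)
    expect_gt(fit@cfi, 0.99)
    expect_lt(fit@rmsea, 0.03)
    expect_lt(fit@srmr, 0.03)
})

test_that("the CFA optimum is at least as good as an independent optimizer", {
    m <- trueCfaModel()
    x <- simulateFromCfa(m, 600, seed = 52)
    S <- cor(x)
    pat <- patternOf(m)
    fit <- fitCfa(S, pat, nObs = 600)
    # independent route: generic Nelder-Mead on the same discrepancy from
    # the same starting values
    mask <- pat@freeMask
    p <- nrow(mask); k <- ncol(mask)
    obj <- function(par) {
        lam <- matrix(0, p, k); lam[mask] <- par[seq_len(sum(mask))]
        phi <- diag(k); phi[upper.tri(phi)] <- par[sum(mask) + 1:3]
        phi[lower.tri(phi)] <- t(phi)[lower.tri(phi)]
        theta <- exp(par[(sum(mask) + 4):(sum(mask) + 3 + p)])
        Sigma <- lam %*% phi %*% t(lam) + diag(theta)
        ch <- tryCatch(chol(Sigma), error = function(e) NULL)
        if (is.null(ch)) return(1e8)
        sum(S * chol2inv(ch)) + 2 * sum(log(diag(ch))) -
            determinant(S)$modulus - p
    }
    start <- c(pat@startLoadings[mask], rep(0, 3),
               log(pmax(1 - rowSums(pat@startLoadings^2), 0.2)))
    ref <- optim(start, obj, method = "Nelder-Mead",
                 control = list(maxit = 20000))
    expect_lte(fit@fml, ref$value + 1e-6)
})

test_that("the independence baseline has its closed form", {
    m <- trueCfaModel()
    expect_equal(unname(baselineModel(diag(4), 100)["chiSquare"]), 0)
    expect_identical(unname(baselineModel(diag(4), 100)["df"]), 6)
    S2 <- matrix(c(1, 0.5, 0.5, 1), 2)
    out <- baselineModel(S2, 101)
    expect_equal(unname(out["chiSquare"]), -100 * log(0.75),
                 tolerance = 1e-12)
    expect_identical(unname(out["df"]), 1)
    expect_error(baselineModel(matrix(1, 3, 3), 50), "singular")
})

test_that("fit indices follow their closed forms", {
    v <- fitIndexValues(100, 50, 1000, 60, 101)
    expect_equal(v$cfi, 1 - 50 / 940, tolerance = 1e-12)
    expect_equal(v$tli, (1000 / 60 - 2) / (1000 / 60 - 1),
                 tolerance = 1e-12)
    expect_equal(v$rmsea, 0.1, tolerance = 1e-12)
    # chi-square at or below df: perfect parsimony-corrected fit
    v2 <- fitIndexValues(40, 50, 1000, 60, 101)
    expect_identical(v2$rmsea, 0)
    expect_identical(v2$cfi, 1)
    # the CI brackets the point estimate and narrows with n
    expect_lte(v$rmseaCi90[1], v$rmsea)
    expect_gte(v$rmseaCi90[2], v$rmsea)
    vBig <- fitIndexValues(1000, 500, 10000, 600, 1001)
    expect_lt(diff(vBig$rmseaCi90), diff(v$rmseaCi90))
})

test_that("SRMR is zero when the model reproduces the sample exactly", {
    m <- trueCfaModel()
    fit <- new("CfaFit", loadings = m$Lam, residualVariances = m$Theta,
               factorCov = m$Phi, implied = m$Sigma, sampleCov = m$Sigma,
               fml = 0, chiSquare = 0, df = 51L,
               baselineChiSquare = 1000, baselineDf = 66L,
               cfi = NA_real_, tli = NA_real_, rmsea = NA_real_,
               rmseaCi90 = c(NA_real_, NA_real_), srmr = NA_real_,
               nObs = 500L, converged = TRUE)
    out <- fitIndices(fit)
    expect_identical(out@srmr, 0)
    expect_identical(out@rmsea, 0)
    expect_identical(out@cfi, 1)
})

test_that("omitting cross-loadings degrades the fit indices monotonically", {
    base <- trueCfaModel()
    fits <- lapply(c(0, 0.25, 0.45), function(cross) {
        m <- base
        m$Lam[5, 1] <- cross          # cross-loading the pattern omits
        m$Lam[9, 2] <- cross
        m$Theta <- pmax(1 - diag(m$Lam %*% m$Phi %*% t(m$Lam)), 0.1)
        m$Sigma <- m$Lam %*% m$Phi %*% t(m$Lam) + diag(m$Theta)
        x <- simulateFromCfa(m, 800, seed = 53)
        fitCfa(cor(x), patternOf(base), nObs = 800)
    })
    cfis <- vapply(fits, function(f) f@cfi, numeric(1))
    rmseas <- vapply(fits, function(f) f@rmsea, numeric(1))
    expect_true(all(diff(cfis) < 0))
    expect_true(all(diff(rmseas) > 0))
})
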