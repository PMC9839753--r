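# Exact planted covariance used by several blocks below.
plantedCovariance <- function() {
    L <- matrix(0, 16, 4)
    L[1:4, 1] <- 0.8; L[5:8, 2] <- 0.75; L[9:12, 3] <- 0.7
    L[13:16, 4] <- 0.65
    psi <- 1 - rowSums(L^2)
    list(L = L, psi = psi, S = tcrossprod(L) + diag(psi))
}

test_that("identity correlation yields no common factors", {
    sol <- fitMlFactors(diag(5), k = 1, nObs = 100)
    expect_lt(max(abs(loadings(sol))), 1e-3)
    expect_lt(max(abs(uniquenesses(sol) - 1)), 1e-3)
})

test_that("an exactly factor-structured covariance is recovered", {
    pl <- plantedCovariance()
    sol <- fitMlFactors(pl$S, k = 4, nObs = 1000)
    expect_lt(mlDiscrepancy(pl$S, reconstructCovariance(sol)), 1e-8)
    rot <- rotateSolution(sol)
    mt <- matchFactors(pl$L, loadings(rot))
    for (f in 1:4) {
        aligned <- loadings(rot)[, mt$permutation[f]] * mt$signs[f]
        expect_gt(congruence(pl$L[, f], aligned), 0.999)
    }
})

test_that("the optimizer is at least as good as an independent minimizer", {
    dat <- makePlantedData(300, nFactors = 3, varsPerFactor = 5,
                           loading = 0.7, seed = 31)
    S <- cor(dat$x)
    k <- 3
    p <- ncol(S)
    sol <- fitMlFactors(S, k, nObs = 300)
    # independent route: generic Nelder-Mead over log-uniquenesses with the
    # conditional eigen-device loadings, from the same textbook start
    objective <- function(logpsi) {
        psi <- exp(logpsi)
        sc <- 1 / sqrt(psi)
        e <- eigen(S * outer(sc, sc), symmetric = TRUE)
        lam <- pmax(e$values[1:k] - 1, 0)
        L <- (e$vectors[, 1:k] * rep(sqrt(lam), each = p)) * sqrt(psi)
        Sigma <- tcrossprod(L) + diag(psi)
        B <- (S - Sigma) %*% solve(Sigma)
        0.5 * sum(B * t(B))
    }
    start <- log(pmin(pmax((1 - 0.5 * k / p) / diag(solve(S)), 0.01), 1))
    ref <- optim(start, objective, method = "Nelder-Mead",
                 control = list(maxit = 5000))
    expect_lte(sol@discrepancy, ref$value + 1e-6)
})

test_that("varimax preserves communalities and fixes simple structure", {
    pl <- plantedCovariance()
    # already-simple loadings change only by permutation/sign
    rot <- varimaxRotate(pl$L)
    mt <- matchFactors(pl$L, rot)
    expect_equal(sort(mt$permutation), 1:4)
    expect_equal(unname(mt$correlations), rep(1, 4), tolerance = 1e-6)
    # row communalities invariant for arbitrary matrices
    set.seed(1)
    L <- matrix(rnorm(30), 10, 3)
    expect_lt(max(abs(rowSums(varimaxRotate(L)^2) - rowSums(L^2))), 1e-10)
    # k = 1 passthrough
    expect_identical(varimaxRotate(pl$L[, 1, drop = FALSE]),
                     pl$L[, 1, drop = FALSE])
})

test_that("varimax at k = 2 matches a fine rotation-angle grid search", {
    set.seed(7)
    L <- matrix(rnorm(16), 8, 2)
    rot <- varimaxRotate(L)
    thetas <- seq(0, pi / 2, by = 1e-4)
    crits <- vapply(thetas, function(th) {
        R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
        varimaxCriterion(L %*% R)
    }, numeric(1))
    best <- max(crits)
    # grid resolution 1e-4 localizes the optimum of the smooth criterion
    expect_gte(varimaxCriterion(rot), best - 1e-6)
    expect_lt(abs(varimaxCriterion(rot) - best), 1e-6)
    # the rotation recovered from the loadings is orthogonal
    R <- solve(crossprod(L), crossprod(L, rot))
    expect_lt(max(abs(crossprod(R) - diag(2))), 1e-8)
})

test_that("explained variance is the column sum of squared loadings", {
    expect_identical(explainedVariance(cbind(rep(0, 5))), 0)
    expect_equal(unname(explainedVariance(cbind(rep(0.5, 4)))), 1)
    set.seed(2)
    L <- matrix(rnorm(30), 10, 3)
    direct <- apply(L, 2, function(col) sum(col * col))
    expect_equal(explainedVariance(L), direct)
    expect_equal(explainedVariance(L, percent = TRUE), 100 * direct / 10)
})

test_that("covariance reconstruction follows the factor decomposition", {
    pl <- plantedCovariance()
    sol <- new("FactorSolution", loadings = pl$L, uniquenesses = pl$psi,
               explainedVariance = colSums(pl$L^2), nFactors = 4L,
               rotated = FALSE, converged = TRUE, nObs = 100L,
               discrepancy = 0)
    expect_equal(reconstructCovariance(sol), pl$S, tolerance = 1e-12)
    # no factors: Sigma reduces to the uniqueness diagonal
    sol0 <- new("FactorSolution", loadings = matrix(0, 4, 1),
                uniquenesses = c(1, 2, 3, 4),
                explainedVariance = 0, nFactors = 1L, rotated = FALSE,
                converged = TRUE, nObs = 10L, discrepancy = 0)
    expect_equal(reconstructCovariance(sol0), diag(c(1, 2, 3, 4)))
    # rotation never changes the reconstructed covariance
    fit <- fitMlFactors(pl$S, 4, 100)
    expect_equal(reconstructCovariance(rotateSolution(fit)),
                 reconstructCovariance(fit), tolerance = 1e-8)
})

test_that("ML discrepancy matches hand values, orthogonal-congruence invariant", {
    expect_identical(mlDiscrepancy(diag(3), diag(3)), 0)
    expect_equal(mlDiscrepancy(diag(c(2, 1)), diag(2)), 0.5)
    expect_error(mlDiscrepancy(diag(2), matrix(0, 2, 2)), "singular")
    set.seed(3)
    for (rep in 1:5) {
        A <- crossprod(matrix(rnorm(36), 6))
        B <- crossprod(matrix(rnorm(36), 6)) + diag(6)
        Q <- qr.Q(qr(matrix(rnorm(36), 6)))
        expect_equal(mlDiscrepancy(Q %*% A %*% t(Q), Q %*% B %*% t(Q)),
                     mlDiscrepancy(A, B), tolerance = 1e-9)
    }
})

test_that("Bartlett scores recover factors and match a per-subject WLS solve", {
    # near-noiseless: scores track the generating factor
    L <- matrix(0.95, 6, 1)
    spec <- syntheticSpec(500, loadings = L,
                          uniquenesses = rep(0.005, 6), seed = 13)
    out <- generateFactorData(spec)
    x <- scale(behavioralValues(out$table))
    # uniquenesses this small sit on the Heywood floor by construction
    sol <- suppressWarnings(efa(x, 1))
    sc <- bartlettScores(x, sol)
    expect_identical(dim(sc), c(500L, 1L))
    expect_gt(abs(cor(sc[, 1], out$truth$factorScores[, 1])), 0.999)

    # row-by-row weighted least squares oracle
    dat <- makePlantedData(200, nFactors = 3, varsPerFactor = 5,
                           loading = 0.7, seed = 14)
    sol3 <- efa(dat$x, 3)
    sc3 <- bartlettScores(dat$x, sol3)
    Lw <- loadings(sol3)
    w <- 1 / uniquenesses(sol3)
    for (i in c(1, 57, 200)) {
        ref <- lm.wfit(Lw, dat$x[i, ], w)$coefficients
        expect_equal(unname(sc3[i, ]), unname(ref), tolerance = 1e-8)
    }
})

test_that("loadings converge to the planted pattern as n grows", {
    dat <- makePlantedData(600, nFactors = 4, varsPerFactor = 10,
                           loading = 0.65, seed = 15)
    sol <- efa(dat$x, 4)
    mt <- matchFactors(dat$spec@loadings, loadings(sol))
    expect_true(all(mt$correlations > 0.95))
    # percent variance is monotone in k and bounded by the variable count
    pv <- vapply(1:5, function(k)
        sum(explainedVariance(efa(dat$x, k))), numeric(1))
    expect_true(all(diff(pv) > -1e-6))
    expect_lt(pv[5], ncol(dat$x))
})
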