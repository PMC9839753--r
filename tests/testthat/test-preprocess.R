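makeToyTable <- function() {
    set.seed(42)
    n <- 60
    base <- rnorm(n)
    df <- data.frame(
        good1 = base + rnorm(n, sd = 0.5),
        good2 = base + rnorm(n, sd = 0.5),
        good3 = -base + rnorm(n, sd = 0.5),
        lonely = rnorm(n) * 1e-8 + 5,          # constant-ish, uncorrelated
        holey = base + rnorm(n),
        comp = base * 2,
        adj = base + 1,
        label = sample(letters, n, replace = TRUE))
    df$lonely <- 5                              # exactly constant
    df$holey[1:8] <- NA                         # 13.3% missing
    BehavioralTable(df,
        variableMeta = data.frame(
            category = "toy",
            isErrorMeasure = FALSE,
            isComposite = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
                            FALSE, FALSE),
            isAdjusted = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                           TRUE, FALSE)),
        confounds = data.frame(age = sample(22:37, n, TRUE),
                               gender = rbinom(n, 1, 0.5)))
}

test_that("variable screening applies every criterion with reasons", {
    out <- selectVariables(makeToyTable())
    rep <- out$report
    expect_setequal(rep$kept, c("good1", "good2", "good3"))
    reason <- setNames(rep$dropped$reason, rep$dropped$variable)
    expect_identical(reason[["holey"]], "missing_ge_10pct")
    expect_identical(reason[["lonely"]], "no_correlation_gt_0.1")
    expect_identical(reason[["comp"]], "composite")
    expect_identical(reason[["adj"]], "adjusted_duplicate")
    expect_identical(reason[["label"]], "non_numeric")
    # kept + dropped partition the input variables
    expect_setequal(c(rep$kept, rep$dropped$variable),
                    c("good1", "good2", "good3", "lonely", "holey",
                      "comp", "adj", "label"))
    expect_length(intersect(rep$kept, rep$dropped$variable), 0)
})

test_that("screening fails loudly when nothing survives", {
    df <- data.frame(a = rep(1, 20), b = rep(2, 20))
    expect_error(selectVariables(BehavioralTable(df)), "all variables")
})

test_that("family-preserving split balances subjects, keeps families intact", {
    # all singletons: exact halves
    dat <- makePlantedData(100, nFactors = 2, varsPerFactor = 3,
                           loading = 0.7, seed = 1)
    tab <- dat$table
    colData(tab)$familyId <- sprintf("f%03d", 1:100)
    halves <- splitByFamily(tab, seed = 5)
    expect_identical(ncol(halves$discovery), 50L)
    expect_identical(ncol(halves$replication), 50L)

    # sizes {3,3,2,2}: only 5/5 splits preserve families
    tab10 <- tab[, 1:10]
    colData(tab10)$familyId <- rep(c("A", "B", "C", "D"), c(3, 3, 2, 2))
    for (s in 1:20) {
        h <- splitByFamily(tab10, seed = s)
        expect_identical(ncol(h$discovery), 5L)
        expect_length(intersect(familyId(h$discovery),
                                familyId(h$replication)), 0)
    }
})

test_that("chained imputation completes tables and beats mean imputation", {
    # identity on complete data
    dat <- makePlantedData(80, nFactors = 2, varsPerFactor = 3,
                           loading = 0.7, seed = 3)
    expect_identical(imputeChained(dat$table, seed = 1), dat$table)

    # two strongly correlated variables, MCAR on one
    set.seed(99)
    n <- 400
    f <- rnorm(n)
    x <- cbind(a = f + rnorm(n, sd = sqrt(1 - 0.9)) * 0,
               b = 0.95 * f + rnorm(n, sd = 0.3),
               c = rnorm(n))
    x[, "a"] <- f + rnorm(n, sd = 0.3)
    tab <- BehavioralTable(x)
    mask <- sample(n, 40)                      # 10% of variable a
    vals <- behavioralValues(tab)
    truth <- vals[mask, "a"]
    vals[mask, "a"] <- NA
    tabNA <- BehavioralTable(vals, confounds = NULL)
    done <- imputeChained(tabNA, seed = 7)
    filled <- behavioralValues(done)
    expect_false(anyNA(filled))
    # observed entries unchanged
    expect_identical(filled[-mask, ], vals[-mask, ])
    rmse <- sqrt(mean((filled[mask, "a"] - truth)^2))
    rmseMean <- sqrt(mean((mean(vals[, "a"], na.rm = TRUE) - truth)^2))
    expect_lt(rmse, rmseMean)
    # deterministic given seed
    expect_identical(behavioralValues(imputeChained(tabNA, seed = 7)),
                     filled)
    # fully missing variable rejected
    vals2 <- vals; vals2[, "c"] <- NA
    expect_error(imputeChained(BehavioralTable(vals2), seed = 1),
                 "fully missing")
})

test_that("confound regression leaves residuals orthogonal to confounds", {
    dat <- makePlantedData(200, nFactors = 2, varsPerFactor = 4,
                           loading = 0.7, seed = 9)
    tab <- dat$table
    vals <- behavioralValues(tab)
    conf <- as.data.frame(confounds(tab))
    # a variable that is exactly 2 * age vanishes
    vals[, 1] <- 2 * conf$age
    # a variable orthogonal to [1, age, gender] comes back centered
    X <- cbind(1, conf$age, conf$gender)
    v <- rnorm(200)
    v <- v - X %*% solve(crossprod(X), crossprod(X, v))
    vals[, 2] <- v + 10            # re-add a mean; projection removes it
    tab <- BehavioralTable(vals, confounds = conf, familyId = familyId(tab))
    res <- behavioralValues(regressConfounds(tab))
    expect_lt(max(abs(res[, 1])), 1e-10)
    expect_lt(max(abs(res[, 2] - v)), 1e-10)
    ageC <- conf$age - mean(conf$age)
    genC <- conf$gender - mean(conf$gender)
    for (j in seq_len(ncol(res))) {
        # orthogonality in the normal-equations sense; correlation where
        # the residual is not degenerate
        expect_lt(abs(mean(res[, j] * ageC)), 1e-10)
        expect_lt(abs(mean(res[, j] * genC)), 1e-10)
        if (sd(res[, j]) > 1e-8) {
            expect_lt(abs(cor(res[, j], conf$age)), 1e-10)
            expect_lt(abs(cor(res[, j], conf$gender)), 1e-10)
        }
    }
})

test_that("error-measure inversion is a sign flip and an involution", {
    dat <- makePlantedData(50, nFactors = 2, varsPerFactor = 3,
                           loading = 0.7, seed = 4)
    tab <- dat$table
    rowData(tab)$isErrorMeasure <- c(TRUE, rep(FALSE, 5))
    flipped <- invertErrorMeasures(tab)
    expect_equal(behavioralValues(flipped)[, 1],
                 -behavioralValues(tab)[, 1])
    expect_equal(behavioralValues(flipped)[, -1],
                 behavioralValues(tab)[, -1])
    expect_equal(behavioralValues(invertErrorMeasures(flipped)),
                 behavioralValues(tab))
})

test_that("z-scoring standardizes exactly and rejects constants by name", {
    dat <- makePlantedData(120, nFactors = 2, varsPerFactor = 4,
                           loading = 0.7, seed = 6)
    z <- behavioralValues(zscoreTable(dat$table))
    expect_lt(max(abs(colMeans(z))), 1e-12)
    expect_lt(max(abs(apply(z, 2, sd) - 1)), 1e-12)
    # idempotent
    z2 <- behavioralValues(zscoreTable(zscoreTable(dat$table)))
    expect_equal(z2, z, tolerance = 1e-12)
    vals <- behavioralValues(dat$table)
    vals[, 3] <- 7
    expect_error(zscoreTable(BehavioralTable(vals)), colnames(vals)[3])
})

test_that("preprocessing chain preserves non-confound correlation structure", {
    # confound-free generation vs confounded generation + regression
    L <- matrix(0, 8, 2); L[1:4, 1] <- 0.7; L[5:8, 2] <- 0.7
    ce <- matrix(rnorm(16, 0, 0.05), 8, 2)
    spec0 <- syntheticSpec(2000, loadings = L, seed = 12)
    spec1 <- syntheticSpec(2000, loadings = L, confoundEffects = ce,
                           seed = 12)
    x0 <- cor(behavioralValues(zscoreTable(generateFactorData(spec0)$table)))
    t1 <- regressConfounds(generateFactorData(spec1)$table)
    x1 <- cor(behavioralValues(zscoreTable(t1)))
    expect_lt(max(abs(x0 - x1)), 0.08)
})
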