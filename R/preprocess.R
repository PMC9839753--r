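#' Screen variables for analysis suitability
#'
#' Applies, in order, the inclusion criteria used for behavioral tables:
#' variables must be numeric, have a missing fraction strictly below
#' `missingThreshold`, must not be composite summaries of other items, must
#' not be the adjusted duplicate of an unadjusted variant, and must show at
#' least one absolute pairwise-complete Pearson correlation above
#' `corThreshold` with another surviving candidate.  The correlation screen
#' runs before imputation, on pairwise-complete observations.
#'
#' @param table a [BehavioralTable-class].
#' @param missingThreshold variables at or above this missing fraction are
#'   dropped (default 0.10).
#' @param corThreshold minimum max absolute correlation with another
#'   candidate (default 0.1, a small effect size).
#' @return a list with `table` (screened [BehavioralTable-class]) and
#'   `report`, a `SelectionReport` (`kept` names plus a `dropped` data frame
#'   of variable/reason pairs; reasons are `non_numeric`,
#'   `missing_ge_10pct`, `composite`, `adjusted_duplicate`,
#'   `no_correlation_gt_0.1`).
#' @export
selectVariables <- function(table, missingThreshold = 0.10,
                            corThreshold = 0.1) {
    vals <- behavioralValues(table)
    meta <- variableMeta(table)
    vars <- colnames(vals)
    reason <- stats::setNames(rep(NA_character_, length(vars)), vars)

    numericOk <- if ("isNumeric" %in% colnames(meta)) meta$isNumeric
                 else rep(TRUE, length(vars))
    reason[!numericOk] <- "non_numeric"
    missFrac <- colMeans(is.na(vals))
    reason[is.na(reason) & missFrac >= missingThreshold] <- "missing_ge_10pct"
    reason[is.na(reason) & meta$isComposite] <- "composite"
    reason[is.na(reason) & meta$isAdjusted] <- "adjusted_duplicate"

    cand <- vars[is.na(reason)]
    if (length(cand) >= 2) {
        cc <- suppressWarnings(
            stats::cor(vals[, cand, drop = FALSE],
                       use = "pairwise.complete.obs"))
        diag(cc) <- 0
        cc[!is.finite(cc)] <- 0
        maxAbs <- apply(abs(cc), 1L, max)
        reason[cand[maxAbs <= corThreshold]] <- "no_correlation_gt_0.1"
    } else if (length(cand) == 1) {
        reason[cand] <- "no_correlation_gt_0.1"
    }

    kept <- vars[is.na(reason)]
    dropped <- data.frame(variable = vars[!is.na(reason)],
                          reason = unname(reason[!is.na(reason)]))
    if (!length(kept))
        stop("all variables were dropped by the selection criteria: ",
             paste(dropped$variable, dropped$reason, sep = " (",
                   collapse = "), "), ")")
    report <- structure(list(kept = kept, dropped = dropped),
                        class = "SelectionReport")
    list(table = table[kept, ], report = report)
}

#' @export
print.SelectionReport <- function(x, ...) {
    cat("SelectionReport:", length(x$kept), "kept,", nrow(x$dropped),
        "dropped\n")
    if (nrow(x$dropped)) print(table(x$dropped$reason))
    invisible(x)
}

#' Write a selection report as JSON
#'
#' @param report a `SelectionReport` from [selectVariables()].
#' @param path output file.
#' @export
writeSelectionReport <- function(report, path) {
    jsonlite::write_json(list(kept = report$kept, dropped = report$dropped),
                         path, dataframe = "rows", digits = NA)
    invisible(path)
}

# Greedy family-preserving bisection: families in decreasing size order
# (seeded tie-break) go to the currently smaller half.
assignFamilies <- function(famIds, seed) {
    sizes <- table(famIds)
    fams <- names(sizes)
    withSeed(seed, {
        ord <- order(-as.integer(sizes), stats::runif(length(fams)))
        inFirst <- logical(length(fams))
        names(inFirst) <- fams
        tot <- c(0L, 0L)
        for (f in fams[ord]) {
            pick <- if (tot[1] < tot[2]) 1L
                    else if (tot[2] < tot[1]) 2L
                    else sample(2L, 1L)
            inFirst[f] <- pick == 1L
            tot[pick] <- tot[pick] + as.integer(sizes[f])
        }
        inFirst
    })
}

#' Split subjects into discovery and replication halves, keeping families
#' intact
#'
#' Siblings always land in the same half, so the two sets share no family.
#' Families are placed greedily by decreasing size onto the smaller half,
#' with seeded random tie-breaking, giving sizes as equal as the family
#' granularity allows.
#'
#' @param table a [BehavioralTable-class] with family identifiers.
#' @param seed integer RNG seed.
#' @return list with `discovery` and `replication` tables.
#' @export
splitByFamily <- function(table, seed) {
    fam <- familyId(table)
    if (is.null(fam)) stop("family identifiers are required")
    sizes <- table(fam)
    if (max(sizes) > 0.5 * ncol(table))
        warning("one family holds more than half the subjects; ",
                "the split will be unbalanced")
    inFirst <- assignFamilies(fam, seed)
    sel <- inFirst[fam]
    list(discovery = table[, sel], replication = table[, !sel])
}

#' Impute missing values by chained equations
#'
#' Single-dataset multiple-imputation-style chained equations for
#' continuous variables: missing entries start at column means, then for a
#' fixed number of sweeps each incomplete variable is regressed on all
#' others (observed rows only) and its missing entries are replaced by
#' posterior-predictive draws — residual variance drawn from its scaled
#' inverse-chi-square posterior, coefficients from their Gaussian posterior,
#' plus Gaussian prediction noise.  Observed entries are never altered.
#'
#' @param table a [BehavioralTable-class]; every variable must be under 10%
#'   missing and none fully missing.
#' @param nIterations number of sweeps over the variables (default 10).
#' @param seed integer RNG seed; imputation is deterministic given it.
#' @return the completed table (no `NA` left).
#' @export
imputeChained <- function(table, nIterations = 10, seed) {
    vals <- behavioralValues(table)
    missing <- is.na(vals)
    if (!any(missing)) return(table)
    if (any(colMeans(missing) == 1))
        stop("variable(s) fully missing: ",
             paste(colnames(vals)[colMeans(missing) == 1], collapse = ", "))
    n <- nrow(vals)
    x <- vals
    for (v in which(colSums(missing) > 0))
        x[missing[, v], v] <- mean(vals[, v], na.rm = TRUE)
    incomplete <- which(colSums(missing) > 0)
    incomplete <- incomplete[order(colSums(missing)[incomplete])]
    withSeed(seed, {
        for (it in seq_len(nIterations)) {
            for (v in incomplete) {
                obs <- !missing[, v]
                X <- cbind(1, x[, -v, drop = FALSE])
                XtX <- crossprod(X[obs, , drop = FALSE])
                Rc <- tryCatch(chol(XtX), error = function(e)
                    chol(XtX + diag(1e-8 * max(diag(XtX)), ncol(XtX))))
                Xty <- crossprod(X[obs, , drop = FALSE], x[obs, v])
                beta <- backsolve(Rc, forwardsolve(t(Rc), Xty))
                res <- x[obs, v] - X[obs, , drop = FALSE] %*% beta
                dfres <- max(sum(obs) - length(beta), 1L)
                sigma2 <- sum(res^2) / stats::rchisq(1L, dfres)
                betaStar <- beta + backsolve(
                    Rc, stats::rnorm(length(beta))) * sqrt(sigma2)
                mis <- missing[, v]
                x[mis, v] <- X[mis, , drop = FALSE] %*% betaStar +
                    stats::rnorm(sum(mis), 0, sqrt(sigma2))
            }
        }
        x[!missing] <- vals[!missing]
        setBehavioralValues(table, x)
    })
}

#' Regress age and gender out of every variable
#'
#' Each variable is replaced by its residual from an ordinary least-squares
#' fit on intercept + age + gender, so downstream factor structure cannot be
#' driven by these confounds.  Residuals are exactly orthogonal to the
#' retained predictors.  Constant confounds are dropped with a warning.
#'
#' @param table a complete (no `NA`) [BehavioralTable-class] with `age` and
#'   `gender` in its confounds.
#' @return the table of residuals.
#' @export
regressConfounds <- function(table) {
    vals <- behavioralValues(table)
    if (anyNA(vals)) stop("impute missing values before confound regression")
    conf <- as.data.frame(confounds(table))
    use <- intersect(c("age", "gender"), colnames(conf))
    if (!length(use)) stop("confounds 'age'/'gender' not found")
    X <- as.matrix(conf[, use, drop = FALSE])
    const <- apply(X, 2L, function(z) stats::var(z) == 0)
    if (any(const)) {
        warning("constant confound(s) dropped: ",
                paste(use[const], collapse = ", "))
        X <- X[, !const, drop = FALSE]
    }
    X <- cbind(intercept = 1, X)
    Q <- qr.Q(qr(X))
    res <- vals - Q %*% crossprod(Q, vals)
    setBehavioralValues(table, res)
}

#' Invert error measures
#'
#' Sign-flips variables flagged `isErrorMeasure` (reaction times, error
#' counts) so that for every variable larger means better.  A sign flip
#' preserves correlation magnitudes — the quantity factor analysis consumes
#' — and is an involution.  Set `reciprocal = TRUE` for 1/x inversion
#' instead.
#'
#' @param table a [BehavioralTable-class].
#' @param reciprocal use `1/x` rather than `-x` (requires nonzero values).
#' @return the table with flagged variables inverted.
#' @export
invertErrorMeasures <- function(table, reciprocal = FALSE) {
    flag <- variableMeta(table)$isErrorMeasure
    if (!any(flag)) return(table)
    vals <- behavioralValues(table)
    vals[, flag] <- if (reciprocal) 1 / vals[, flag] else -vals[, flag]
    setBehavioralValues(table, vals)
}

#' Z-score every variable across subjects
#'
#' Centers and scales each variable to mean 0 and unit standard deviation
#' (n - 1 denominator).  Constant variables are an error, reported by name.
#'
#' @param table a complete [BehavioralTable-class].
#' @return the standardized table.
#' @export
zscoreTable <- function(table) {
    vals <- behavioralValues(table)
    if (anyNA(vals)) stop("impute missing values before z-scoring")
    sds <- apply(vals, 2L, stats::sd)
    if (any(sds == 0))
        stop("constant variable(s) cannot be z-scored: ",
             paste(colnames(vals)[sds == 0], collapse = ", "))
    setBehavioralValues(table, scale(vals)[, , drop = FALSE])
}
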