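# Internal helpers shared across modules.

# Run code with a local RNG seed, restoring the caller's RNG state afterwards
# so that analysis functions are deterministic without clobbering the session.
withSeed <- function(seed, code) {
    if (!is.null(seed)) {
        has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
        if (has) {
            old <- get(".Random.seed", envir = globalenv())
            on.exit(assign(".Random.seed", old, envir = globalenv()),
                    add = TRUE)
        } else {
            on.exit(suppressWarnings(
                rm(".Random.seed", envir = globalenv())), add = TRUE)
        }
        set.seed(as.integer(seed))
    }
    force(code)
}

upperTriVals <- function(m) m[upper.tri(m)]

# K-means with restarts; retries on the rare "initial centers are not
# distinct" failure that random initialization can produce.
safeKmeans <- function(x, K, nInit, iterMax = 100L) {
    for (attempt in seq_len(6L)) {
        res <- tryCatch(
            suppressWarnings(stats::kmeans(x, centers = K, nstart = nInit,
                                           iter.max = iterMax)),
            error = function(e) NULL)
        if (!is.null(res)) return(res)
    }
    stop("K-means failed repeatedly (K = ", K, ", n = ", nrow(x), ")")
}

# Order factors by decreasing explained variance and set each factor's sign
# so that its largest-magnitude loading is positive.
orderAndSign <- function(L) {
    ev <- colSums(L^2)
    L <- L[, order(ev, decreasing = TRUE), drop = FALSE]
    for (f in seq_len(ncol(L))) {
        s <- sign(L[which.max(abs(L[, f])), f])
        if (s < 0) L[, f] <- -L[, f]
    }
    colnames(L) <- paste0("F", seq_len(ncol(L)))
    L
}
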