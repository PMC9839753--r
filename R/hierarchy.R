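#' Build the cross-level factor hierarchy
#'
#' Fits rotated factor solutions for every dimensionality `1..kMax`,
#' computes Bartlett factor scores at each level, and correlates scores
#' between consecutive levels.  The absolute correlation between a factor
#' at level `k` and one at level `k + 1` is the "flow" of variance from
#' parent to child — the data behind a Sankey diagram of how broad domains
#' split into narrower ones as dimensionality grows.
#'
#' @param data subjects x variables standardized matrix.
#' @param kMax deepest level (number of factors) of the hierarchy;
#'   must be at least 2.
#' @param ... passed to [efa()].
#' @return a `HierarchyFlow` list: `levels` (list of
#'   [FactorSolution-class]), `edges` (data frame `level`, `parent`,
#'   `child`, `weight` with weights in \[0, 1\] linking level `k` to
#'   `k + 1`), and `percentVariance` (per-level named vectors).
#' @export
buildHierarchy <- function(data, kMax, ...) {
    if (kMax < 2) stop("'kMax' must be at least 2")
    sols <- lapply(seq_len(kMax), function(k) efa(data, k, ...))
    scores <- vector("list", kMax)
    for (k in seq_len(kMax)) {
        if (!sols[[k]]@converged) {
            warning("level k = ", k, " did not converge; ",
                    "its edges are omitted")
            next
        }
        scores[[k]] <- bartlettScores(data, sols[[k]])
    }
    edges <- NULL
    for (k in seq_len(kMax - 1L)) {
        if (is.null(scores[[k]]) || is.null(scores[[k + 1L]])) next
        W <- abs(stats::cor(scores[[k]], scores[[k + 1L]]))
        edges <- rbind(edges, data.frame(
            level = k,
            parent = rep(seq_len(k), times = k + 1L),
            child = rep(seq_len(k + 1L), each = k),
            weight = as.vector(W)))
    }
    pv <- lapply(sols, explainedVariance, percent = TRUE)
    structure(list(levels = sols, edges = edges, percentVariance = pv),
              class = "HierarchyFlow")
}

#' @export
print.HierarchyFlow <- function(x, ...) {
    kMax <- length(x$levels)
    cat("HierarchyFlow over", kMax, "levels;",
        if (is.null(x$edges)) 0L else nrow(x$edges), "edges\n")
    for (k in seq_len(kMax))
        cat(sprintf("  k=%d: total %.1f%% variance\n", k,
                    sum(x$percentVariance[[k]])))
    invisible(x)
}

#' Export a factor hierarchy for Sankey plotting
#'
#' Writes `<prefix>_edges.csv` (level, parent, child, weight) and
#' `<prefix>_sankey.json` with `nodes` (one per factor per level, labeled
#' with its percent variance) and `links` (source/target/value), directly
#' consumable by standard Sankey tools.
#'
#' @param flow a `HierarchyFlow` from [buildHierarchy()].
#' @param prefix file path prefix.
#' @export
writeHierarchy <- function(flow, prefix) {
    utils::write.csv(flow$edges, paste0(prefix, "_edges.csv"),
                     row.names = FALSE)
    nodes <- do.call(rbind, lapply(seq_along(flow$levels), function(k)
        data.frame(id = paste0("k", k, "_F", seq_len(k)),
                   level = k, factor = seq_len(k),
                   percentVariance = flow$percentVariance[[k]])))
    ids <- stats::setNames(seq_len(nrow(nodes)) - 1L, nodes$id)
    links <- data.frame(
        source = unname(ids[paste0("k", flow$edges$level, "_F",
                                   flow$edges$parent)]),
        target = unname(ids[paste0("k", flow$edges$level + 1L, "_F",
                                   flow$edges$child)]),
        value = flow$edges$weight)
    jsonlite::write_json(list(nodes = nodes, links = links),
                         paste0(prefix, "_sankey.json"),
                         dataframe = "rows", digits = NA)
    invisible(prefix)
}
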