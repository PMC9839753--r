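#' Pipeline configuration
#'
#' Collects every tunable of the discovery/replication workflow with the
#' defaults used throughout the package: the 10% missingness and r > 0.1
#' screening thresholds, 80% subsampling fractions, 1000-iteration
#' resampling loops, 20 parallel-analysis repetitions, 10 K-means
#' restarts, the 0.4 interpretability and 0.45 CFA-indicator loading
#' cutoffs, and one explicit seed for every stochastic stage (derived from
#' `seed`).
#'
#' @param seed master integer seed; stage seeds are fixed offsets of it.
#' @param ... overrides for any configuration entry (see the returned
#'   list's names).
#' @return a named list of settings.
#' @export
pipelineConfig <- function(seed = 1L, ...) {
    cfg <- list(
        seed = as.integer(seed),
        missingThreshold = 0.10,
        corThreshold = 0.1,
        loadingThreshold = 0.4,
        minVariables = 3,
        cfaThreshold = 0.45,
        imputeIterations = 10,
        parallelReps = 20,
        robustnessIterations = 1000,
        robustnessFraction = 0.8,
        robustnessThreshold = 0.9,
        consensusIterations = 1000,
        consensusFraction = 0.8,
        kmeansInit = 10,
        kMaxCap = 15L,
        factorCovFree = TRUE)
    dots <- list(...)
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
        stop("unknown configuration entries: ",
             paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
    cfg
}

writeStage <- function(outDir, stage, writer) {
    if (is.null(outDir)) return(NULL)
    path <- file.path(outDir, stage)
    writer(path)
    stage
}

#' Run the full discovery/replication study
#'
#' Orchestrates the complete workflow on a behavioral table: variable
#' screening, a family-preserving split into discovery and replication
#' halves, per-half preprocessing (chained imputation, confound
#' regression, error-measure inversion, z-scoring), parallel analysis on
#' the discovery half to bound the dimensionality, per-k factor solutions
#' with robustness and interpretability diagnostics, the factor hierarchy,
#' consensus clustering of variables on both halves with agreement indices
#' (ARI/AMI) between their final labels, factor-loading comparison across
#' halves, and a confirmatory factor analysis of the discovery-derived
#' pattern evaluated on the replication covariance only (never refit on
#' discovery).
#'
#' All stages draw their seeds from `config$seed`, so a rerun with the
#' same table and configuration reproduces every number exactly.
#'
#' @param table a [BehavioralTable-class].
#' @param config a list from [pipelineConfig()].
#' @param outDir optional directory; when given, each stage writes its
#'   artifact (CSV/JSON) there and a `manifest.json` records them.
#' @return a `StudyReport` list with entries `selection`, `split`,
#'   `parallelAnalysis`, `dimensionality`, `solutions`, `hierarchy`,
#'   `consensus` (per-K diagnostics and chosen K), `agreement` (ARI/AMI),
#'   `replicationComparison`, `cfa`, and `manifest`.
#' @export
runFullStudy <- function(table, config = pipelineConfig(), outDir = NULL) {
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    manifest <- list()
    errors <- list()
    note <- function(stage, file) manifest[[stage]] <<- file
    seed <- config$seed

    # --- selection + split ------------------------------------------------
    sel <- selectVariables(table, config$missingThreshold,
                           config$corThreshold)
    note("selection", writeStage(outDir, "selection.json", function(p)
        writeSelectionReport(sel$report, p)))
    halves <- splitByFamily(sel$table, seed = seed + 1L)

    prep <- function(half, s) {
        if (anyNA(behavioralValues(half)))
            half <- imputeChained(half, config$imputeIterations, seed = s)
        if (all(c("age", "gender") %in% colnames(confounds(half))))
            half <- regressConfounds(half)
        half <- invertErrorMeasures(half)
        behavioralValues(zscoreTable(half))
    }
    disc <- prep(halves$discovery, seed + 2L)
    repl <- prep(halves$replication, seed + 3L)
    note("split", writeStage(outDir, "split.json", function(p)
        jsonlite::write_json(list(discovery = rownames(disc),
                                  replication = rownames(repl)), p)))

    # --- dimensionality ---------------------------------------------------
    pa <- parallelAnalysis(disc, nReps = config$parallelReps,
                           seed = seed + 4L)
    kMax <- min(max(2L, pa$crossover), config$kMaxCap,
                ncol(disc) - 1L)
    note("parallelAnalysis", writeStage(outDir, "parallel_analysis.json",
        function(p) jsonlite::write_json(
            pa[c("realValues", "nullMeans", "nReps", "crossover")], p,
            auto_unbox = TRUE, digits = NA)))

    dimrep <- evaluateDimensionality(
        disc, kMax, nIter = config$robustnessIterations,
        fraction = config$robustnessFraction, seed = seed + 5L,
        loadingThreshold = config$loadingThreshold,
        minVariables = config$minVariables,
        robustnessThreshold = config$robustnessThreshold)
    kBest <- attr(dimrep, "recommended")
    if (is.na(kBest)) kBest <- which.max(dimrep$percentVariance)
    note("dimensionality", writeStage(outDir, "dimensionality.csv",
        function(p) utils::write.csv(as.data.frame(dimrep), p,
                                     row.names = FALSE)))

    solutions <- lapply(seq_len(kMax), function(k) efa(disc, k))
    note("efa", writeStage(outDir, "efa_discovery", function(p)
        writeFactorSolution(solutions[[kBest]], p)))

    hier <- tryCatch(buildHierarchy(disc, kMax), error = function(e) {
        errors$hierarchy <<- conditionMessage(e); NULL })
    if (!is.null(hier))
        note("hierarchy", writeStage(outDir, "hierarchy", function(p)
            writeHierarchy(hier, p)))

    # --- consensus clustering on both halves ------------------------------
    KRange <- 2:max(3L, kMax)
    consOf <- function(dataHalf, s) {
        ms <- lapply(KRange, function(K)
            consensusCluster(dataHalf, K,
                             nIter = config$consensusIterations,
                             fraction = config$consensusFraction,
                             nInit = config$kmeansInit, seed = s + K))
        names(ms) <- paste0("K", KRange)
        ms
    }
    consDisc <- consOf(disc, seed + 100L)
    consRepl <- consOf(repl, seed + 200L)
    cs <- vapply(consDisc, consensusScore, numeric(1))
    aucs <- vapply(consDisc, function(m) consensusCdfAuc(m)$auc,
                   numeric(1))
    KBest <- KRange[which.max(cs)]
    labDisc <- finalLabels(consDisc[[paste0("K", KBest)]],
                           seed = seed + 300L,
                           nInit = config$kmeansInit)
    labRepl <- finalLabels(consRepl[[paste0("K", KBest)]],
                           seed = seed + 301L,
                           nInit = config$kmeansInit)
    agreement <- c(ari = adjustedRand(labDisc, labRepl),
                   ami = adjustedMutualInfo(labDisc, labRepl))
    note("consensus", writeStage(outDir, "consensus_discovery",
        function(p) writeConsensus(consDisc[[paste0("K", KBest)]], p,
                                   labels = labDisc)))

    # --- replication: factor comparison + CFA ----------------------------
    replSol <- efa(repl, kBest)
    comparison <- compareSolutions(solutions[[kBest]], replSol)
    note("comparison", writeStage(outDir, "factor_comparison.csv",
        function(p) utils::write.csv(comparison$correlations, p)))

    cfaFit <- tryCatch({
        pat <- patternFromEfa(solutions[[kBest]],
                              threshold = config$cfaThreshold,
                              factorCovFree = config$factorCovFree)
        fitCfa(stats::cor(repl), pat, nObs = nrow(repl))
    }, error = function(e) {
        errors$cfa <<- conditionMessage(e); NULL })
    if (!is.null(cfaFit))
        note("cfa", writeStage(outDir, "cfa_replication.json",
            function(p) writeCfaFit(cfaFit, p)))

    report <- structure(list(
        selection = sel$report, split = list(discovery = rownames(disc),
                                             replication = rownames(repl)),
        parallelAnalysis = pa, dimensionality = dimrep,
        recommendedK = kBest, solutions = solutions, hierarchy = hier,
        consensus = list(KRange = KRange, score = cs, auc = aucs,
                         deltaAuc = deltaAuc(aucs), KBest = KBest,
                         labelsDiscovery = labDisc,
                         labelsReplication = labRepl,
                         matrices = consDisc),
        agreement = agreement, replicationComparison = comparison,
        cfa = cfaFit, errors = errors, config = config,
        manifest = manifest), class = "StudyReport")
    if (!is.null(outDir)) {
        jsonlite::write_json(
            list(stages = manifest,
                 errors = lapply(errors, identity),
                 complete = length(errors) == 0L),
            file.path(outDir, "manifest.json"), auto_unbox = TRUE)
    }
    report
}

#' @export
print.StudyReport <- function(x, ...) {
    cat("StudyReport\n")
    cat("  variables kept:", length(x$selection$kept),
        "| subjects:", length(x$split$discovery), "+",
        length(x$split$replication), "\n")
    cat("  parallel-analysis crossover:", x$parallelAnalysis$crossover,
        "| recommended k:", x$recommendedK,
        "| consensus K:", x$consensus$KBest, "\n")
    cat(sprintf("  cluster agreement: ARI %.3f, AMI %.3f\n",
                x$agreement["ari"], x$agreement["ami"]))
    if (!is.null(x$cfa)) show(x$cfa)
    if (length(x$errors))
        cat("  stages with errors:", paste(names(x$errors),
                                           collapse = ", "), "\n")
    invisible(x)
}
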