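#' Names of the available DA testing methods
#' @return Character vector of method names accepted by the benchmark
#'   drivers.
#' @export
daMethods <- function() c("cydar", "daseq", "meld", "cna", "milo", "louvain")

#' Default benchmark configuration
#'
#' The shipped study conditions: three topologies (linear and branch 7500
#' cells x 500 genes, cluster 2700 x 500 with unbalanced populations
#' M1/M2/M3), DA ratios 0.75/0.85/0.95, three target populations per
#' topology, three planting seeds, top-50-PC embedding, k = 30 graph, and
#' per-method hyperparameters. Values can be overridden via YAML
#' ([readBenchConfig()]) or by editing the returned list.
#'
#' @return A nested configuration list.
#' @export
benchConfig <- function() {
    list(
        simulate = list(
            topologies = list(
                linear = list(nCells = 7500, nGenes = 500),
                branch = list(nCells = 7500, nGenes = 500),
                cluster = list(nCells = 2700, nGenes = 500)),
            dispersion = 0.5,
            p_da = c(0.75, 0.85, 0.95),
            batch_sd = 0,
            seed = 1),
        preprocess = list(n_components = 50, k = 30, kernel = "binary"),
        methods = list(
            cydar = list(centerFraction = 0.1, alpha = 0.1,
                         occupancy = 100),
            daseq = list(kList = seq(50, 500, by = 50), nPermutations = 50),
            meld = list(beta = 60),
            cna = list(steps = 3, nPermutations = 1000, fdr = 0.1),
            milo = list(sampleFraction = 0.1, alpha = 0.1, k = 100),
            louvain = list(resolution = 1, alpha = 0.1)),
        evaluate = list(percentiles = seq(0, 100, by = 1)),
        seeds = 1:3)
}

#' Read a benchmark configuration from YAML
#'
#' Keys present in the file override the defaults from [benchConfig()];
#' everything else keeps its default.
#'
#' @param path YAML file.
#' @return A configuration list.
#' @export
readBenchConfig <- function(path) {
    user <- yaml::read_yaml(path)
    modifyList(benchConfig(), user)
}

#' Default target DA populations per topology
#' @param topology topology name.
#' @return Character vector of three population names.
#' @export
defaultTargets <- function(topology) {
    switch(topology,
           linear = c("P1", "P3", "P5"),
           branch = c("S1", "A2", "B2"),
           cluster = c("M1", "M2", "M3"),
           stop("unknown topology: ", topology))
}

#' Simulate and embed one benchmark dataset
#'
#' Runs [simulateTopology()], [log1pNormalize()] and [pcaEmbed()] with the
#' study defaults for the given topology.
#'
#' @param topology `"linear"`, `"branch"` or `"cluster"`.
#' @param seed master seed.
#' @param nCells,nGenes optional size overrides (defaults: 7500 x 500 for
#'   trajectories, 2700 x 500 for clusters).
#' @param nComponents PCs to keep.
#' @param dispersion NB dispersion.
#' @return A dataset with `logcounts` and a `"PCA"` embedding.
#' @export
simulateBenchDataset <- function(topology, seed = 1, nCells = NULL,
                                 nGenes = 500, nComponents = 50,
                                 dispersion = 0.5) {
    if (is.null(nCells))
        nCells <- if (topology == "cluster") 2700 else 7500
    sce <- simulateTopology(topology, nCells = nCells, nGenes = nGenes,
                            dispersion = dispersion, seed = seed)
    pcaEmbed(log1pNormalize(sce), nComponents = nComponents)
}

# graph-derived inputs shared by all runs on one embedding
.prepareInputs <- function(sce, k, methods, methodParams, kernel = "binary") {
    kMax <- k
    if ("daseq" %in% methods)
        kMax <- max(kMax, methodParams$daseq$kList)
    if ("milo" %in% methods)
        kMax <- max(kMax, methodParams$milo$k %||% k)
    if ("cydar" %in% methods)
        kMax <- max(kMax, methodParams$cydar$occupancy %||% 100)
    kMax <- min(kMax, ncol(sce) - 1)
    knn <- knnSearch(sce, kMax)
    graph <- buildKnnGraph(sce, k = k, kernel = kernel, knn = knn)
    kMilo <- min(methodParams$milo$k %||% k, ncol(sce) - 1)
    list(graph = graph, knn = knn,
         miloGraph = if (!"milo" %in% methods) NULL
                     else if (kMilo == k) graph
                     else buildKnnGraph(sce, k = kMilo, kernel = kernel,
                                        knn = knn),
         filter = if ("meld" %in% methods)
             meldFilter(graph, methodParams$meld$beta),
         clusters = if ("louvain" %in% methods)
             louvainClusters(graph, methodParams$louvain$resolution,
                             seed = 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run one DA method by name
#'
#' Dispatcher used by the benchmark grid; `inputs` carries the shared graph
#' objects from one embedding so repeated runs do not rebuild them.
#'
#' @param method one of [daMethods()].
#' @param x dataset with assigned samples.
#' @param inputs list with `graph` and optionally `knn`, `filter`,
#'   `clusters`.
#' @param params method hyperparameter list (see [benchConfig()]).
#' @param batch logical; use the batch covariate (ignored with a warning for
#'   daseq and meld, which have no batch pathway).
#' @param seed integer seed.
#' @return A \linkS4class{DAResult}.
#' @export
runDAMethod <- function(method, x, inputs, params = list(), batch = FALSE,
                        seed = 1) {
    if (!method %in% daMethods())
        stop("unknown method '", method, "'; available: ",
             paste(daMethods(), collapse = ", "))
    if (batch && method %in% c("daseq", "meld")) {
        warning(method, " has no batch pathway; running without")
        batch <- FALSE
    }
    g <- inputs$graph
    switch(method,
        cydar = do.call(runCydar, c(list(x = x, graph = g,
                                         knn = inputs$knn, batch = batch,
                                         seed = seed), params)),
        daseq = do.call(runDAseq, c(list(x = x, knn = inputs$knn,
                                         seed = seed), params)),
        meld = do.call(runMeld, c(list(x = x, graph = g,
                                       filter = inputs$filter), params)),
        cna = do.call(runCNA, c(list(x = x, graph = g, batch = batch,
                                     seed = seed), params)),
        milo = do.call(runMilo, c(list(x = x,
                                       graph = inputs$miloGraph %||% g,
                                       batch = batch, seed = seed),
                                  params[setdiff(names(params), "k")])),
        louvain = do.call(runLouvain, c(list(x = x, graph = g,
                                             clusters = inputs$clusters,
                                             batch = batch, seed = seed),
                                        params)))
}

#' Run the benchmark grid
#'
#' Executes the full study grid — topology x DA ratio x target population x
#' seed x method (optionally x batch magnitude x batch-covariate setting) —
#' and scores every run against its planted ground truth with the
#' percentile-threshold AUROC/AUPRC protocol. Datasets, embeddings, graphs,
#' Meld filters and Louvain partitions are computed once per embedding and
#' reused; a failing (method, run) pair is logged as a missing record, not a
#' crash.
#'
#' @param topologies topologies to include.
#' @param methods methods to include (see [daMethods()]).
#' @param daRatios DA ratio grid (default 0.75/0.85/0.95).
#' @param seeds planting/assignment seeds (default 1:3).
#' @param targets named list of target populations per topology (default
#'   [defaultTargets()]).
#' @param batchSd batch-magnitude grid (default 0: no batch effects).
#' @param batchCovariate logical vector: run with and/or without the batch
#'   covariate (methods without a batch pathway run only without).
#' @param balancedCluster subsample M2 to M1's size first (cluster only).
#' @param config configuration list (default [benchConfig()]).
#' @param seed master seed; all child streams derive from it.
#' @param verbose print per-run progress.
#' @return A records data.frame (one row per scored run); aggregate with
#'   [aggregateMetrics()].
#' @export
runBenchmarkGrid <- function(topologies = c("linear", "branch", "cluster"),
                             methods = daMethods(),
                             daRatios = c(0.75, 0.85, 0.95),
                             seeds = 1:3, targets = NULL, batchSd = 0,
                             batchCovariate = FALSE,
                             balancedCluster = FALSE,
                             config = benchConfig(), seed = 1,
                             verbose = FALSE) {
    percentiles <- config$evaluate$percentiles
    k <- config$preprocess$k
    recs <- list()
    for (topo in topologies) {
        tcfg <- config$simulate$topologies[[topo]]
        sce0 <- simulateBenchDataset(topo, seed = childSeed(seed, topo),
                                     nCells = tcfg$nCells,
                                     nGenes = tcfg$nGenes,
                                     nComponents =
                                         config$preprocess$n_components,
                                     dispersion = config$simulate$dispersion)
        dsName <- topo
        if (balancedCluster && topo == "cluster") {
            sizes <- table(sce0$population)
            sce0 <- subsamplePopulation(sce0, "M2", as.integer(min(sizes)),
                                        seed = childSeed(seed, "balance"))
            sce0 <- pcaEmbed(sce0,
                             nComponents = config$preprocess$n_components)
            dsName <- "cluster_balanced"
        }
        tg <- if (!is.null(targets)) targets[[topo]] else defaultTargets(topo)
        popShare <- prop.table(table(sce0$population))
        # ground truth is intrinsic: planted on the unshifted embedding
        truths <- list()
        for (target in tg) {
            for (ratio in daRatios) {
                tr <- plantDA(sce0, target, ratio)
                tr <- groundTruthLabels(tr, popShare[[target]])
                truths[[paste(target, ratio)]] <- tr
            }
        }
        useBatch <- any(batchSd > 0) || any(batchCovariate)
        # graph inputs on the unshifted embedding, shared by all
        # batch-free runs
        inputs0 <- .prepareInputs(sce0, k, methods, config$methods,
                                  config$preprocess$kernel)
        for (s in seeds) {
            for (target in tg) for (ratio in daRatios) {
                tr <- truths[[paste(target, ratio)]]
                xr0 <- assignConditions(
                    sce0, tr,
                    seed = childSeed(seed, paste(topo, s, target, ratio)))
                truthBin <- binarizeTruth(tr)
                for (bsd in batchSd) {
                    runTag <- paste(topo, bsd, s, sep = ".")
                    # batches partition whole samples, so the shift (and
                    # hence the graph) is specific to this run's design
                    xr <- if (useBatch)
                        addBatchEffects(xr0, bsd,
                                        seed = childSeed(seed, runTag))
                    else xr0
                    inputs <- if (bsd > 0)
                        .prepareInputs(xr, k, methods, config$methods,
                                       config$preprocess$kernel)
                    else inputs0
                    for (bc in unique(batchCovariate)) for (m in methods) {
                        if (bc && m %in% c("daseq", "meld")) next
                        res <- tryCatch(
                            suppressWarnings(runDAMethod(
                                m, xr, inputs, config$methods[[m]],
                                batch = bc,
                                seed = childSeed(seed,
                                                 paste(runTag, target,
                                                       ratio, m)))),
                            error = function(e) {
                                message("run failed (", m, ", ", runTag,
                                        "): ", conditionMessage(e))
                                NULL
                            })
                        if (is.null(res)) next
                        sc <- cellScore(res)
                        recs[[length(recs) + 1]] <- data.frame(
                            method = m, dataset = dsName, topology = topo,
                            da_ratio = ratio, target_population = target,
                            seed = s, batch_sd = bsd, batch_covariate = bc,
                            auroc = auroc(sc, truthBin, percentiles),
                            auprc = auprc(sc, truthBin, percentiles),
                            n_cells = ncol(xr))
                        if (verbose)
                            message(sprintf(
                                "%s %s target=%s ratio=%.2f seed=%d bsd=%.2f bc=%s AUROC=%.3f",
                                dsName, m, target, ratio, s, bsd, bc,
                                recs[[length(recs)]]$auroc))
                    }
                }
            }
        }
    }
    do.call(rbind, recs)
}

#' Relative-runtime scaling harness
#'
#' Times each method on a series of datasets of increasing size and reports
#' wall times normalized to the smallest size. Informational only.
#'
#' @param sizes cell counts (default a small series).
#' @param methods methods to time.
#' @param config configuration list.
#' @param seed master seed.
#' @return A data.frame with `method`, `n_cells`, `seconds`,
#'   `relative_growth`.
#' @export
benchTiming <- function(sizes = c(1000, 2000), methods = daMethods(),
                        config = benchConfig(), seed = 1) {
    out <- list()
    for (n in sizes) {
        sce <- simulateBenchDataset("linear", seed = childSeed(seed, "scal"),
                                    nCells = n,
                                    nGenes = config$simulate$topologies$
                                        linear$nGenes %||% 500)
        tr <- groundTruthLabels(plantDA(sce, "P1", 0.85), 0.2)
        sce <- assignConditions(sce, tr, seed = childSeed(seed, "scalc"))
        inputs <- .prepareInputs(sce, config$preprocess$k, methods,
                                 config$methods)
        for (m in methods) {
            t0 <- proc.time()[["elapsed"]]
            ok <- !is.null(tryCatch(
                suppressWarnings(runDAMethod(m, sce, inputs,
                                             config$methods[[m]],
                                             seed = seed)),
                error = function(e) NULL))
            out[[length(out) + 1]] <- data.frame(
                method = m, n_cells = n,
                seconds = if (ok) proc.time()[["elapsed"]] - t0 else NA)
        }
    }
    df <- do.call(rbind, out)
    base <- df[df$n_cells == min(sizes), ]
    df$relative_growth <- df$seconds /
        base$seconds[match(df$method, base$method)]
    df
}
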