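# File-based benchmark drivers: the same grid as runBenchmarkGrid(), staged
# through MTX/TSV datasets, TSV results and CSV metrics with JSON manifests,
# so individual stages can be re-run or distributed.

.gridCells <- function(config, topologies, targets, seeds) {
    grid <- list()
    for (topo in topologies) {
        tg <- if (!is.null(targets)) targets[[topo]]
              else defaultTargets(topo)
        for (target in tg)
            for (ratio in config$simulate$p_da)
                for (bsd in config$simulate$batch_sd)
                    for (s in seeds)
                        grid[[length(grid) + 1]] <- list(
                            topology = topo, target = target, ratio = ratio,
                            batch_sd = bsd, seed = s,
                            id = sprintf("%s_%s_r%s_b%s_s%d", topo, target,
                                         ratio, bsd, s))
    }
    grid
}

#' Write the benchmark datasets and ground truths to disk
#'
#' One dataset directory per grid cell (topology x target x DA ratio x
#' batch magnitude x seed), each holding MTX counts, TSV metadata, the PCA
#' embedding and the ground-truth TSV, plus a JSON manifest of the whole
#' plan. Existing output is refused without `force`.
#'
#' @param outDir output directory.
#' @param config configuration list ([benchConfig()]).
#' @param topologies,targets,seeds grid axes (defaults from `config`).
#' @param seed master seed.
#' @param force overwrite existing output.
#' @param dryRun print the plan and write nothing.
#' @return Invisibly, the grid-cell ids.
#' @export
benchSimulate <- function(outDir, config = benchConfig(),
                          topologies = names(config$simulate$topologies),
                          targets = NULL, seeds = config$seeds, seed = 1,
                          force = FALSE, dryRun = FALSE) {
    grid <- .gridCells(config, topologies, targets, seeds)
    if (dryRun) {
        message("would simulate ", length(grid), " dataset(s) under ",
                outDir)
        for (g in grid) message("  ", g$id)
        return(invisible(vapply(grid, `[[`, "", "id")))
    }
    if (dir.exists(outDir) && length(list.files(outDir)) && !force)
        stop(outDir, " exists and is non-empty; use force = TRUE")
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    sceCache <- list()
    for (g in grid) {
        topo <- g$topology
        if (is.null(sceCache[[topo]])) {
            tcfg <- config$simulate$topologies[[topo]]
            sceCache[[topo]] <- simulateBenchDataset(
                topo, seed = childSeed(seed, topo), nCells = tcfg$nCells,
                nGenes = tcfg$nGenes,
                nComponents = config$preprocess$n_components,
                dispersion = config$simulate$dispersion)
        }
        sce <- sceCache[[topo]]
        tr <- plantDA(sce, g$target, g$ratio)
        tr <- groundTruthLabels(tr,
                                prop.table(table(sce$population))[[g$target]])
        runTag <- paste(topo, g$batch_sd, g$seed, sep = ".")
        sce <- assignConditions(sce, tr,
                                seed = childSeed(seed, paste(runTag,
                                                             g$target,
                                                             g$ratio)))
        if (g$batch_sd > 0)
            sce <- addBatchEffects(sce, g$batch_sd,
                                   seed = childSeed(seed, runTag))
        d <- file.path(outDir, g$id)
        writeDataset(sce, d)
        writeGroundTruth(tr, file.path(d, "truth.tsv"))
    }
    jsonlite::write_json(list(seed = seed,
                              cells = lapply(grid, function(g)
                                  g[c("id", "topology", "target", "ratio",
                                      "batch_sd", "seed")])),
                         file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(vapply(grid, `[[`, "", "id"))
}

#' Run DA methods over datasets written by [benchSimulate()]
#'
#' Results land beside each dataset as `<method>_cells.tsv` etc.; completed
#' runs (manifest present) are skipped, and a failing run is logged and
#' recorded as missing rather than aborting the grid.
#'
#' @param outDir the [benchSimulate()] output directory.
#' @param methods methods to run.
#' @param config configuration list.
#' @param batch use the batch covariate where available.
#' @param seed master seed.
#' @return Invisibly, a data.frame of run statuses.
#' @export
benchRun <- function(outDir, methods = daMethods(), config = benchConfig(),
                     batch = FALSE, seed = 1) {
    bad <- setdiff(methods, daMethods())
    if (length(bad))
        stop("unknown method(s) ", paste(bad, collapse = ", "),
             "; available: ", paste(daMethods(), collapse = ", "))
    manifest <- jsonlite::read_json(file.path(outDir, "manifest.json"))
    status <- list()
    for (cell in manifest$cells) {
        d <- file.path(outDir, cell$id)
        sce <- readDataset(d)
        inputs <- NULL
        for (m in methods) {
            prefix <- file.path(d, m)
            if (file.exists(paste0(prefix, "_manifest.json"))) {
                status[[length(status) + 1]] <-
                    data.frame(id = cell$id, method = m, status = "cached")
                next
            }
            if (is.null(inputs))
                inputs <- .prepareInputs(sce, config$preprocess$k, methods,
                                         config$methods,
                                         config$preprocess$kernel)
            res <- tryCatch(
                suppressWarnings(runDAMethod(
                    m, sce, inputs, config$methods[[m]], batch = batch,
                    seed = childSeed(seed, paste(cell$id, m)))),
                error = function(e) {
                    message("run failed (", cell$id, ", ", m, "): ",
                            conditionMessage(e)); NULL
                })
            if (!is.null(res)) writeDAResult(res, prefix, colnames(sce))
            status[[length(status) + 1]] <- data.frame(
                id = cell$id, method = m,
                status = if (is.null(res)) "failed" else "ok")
        }
    }
    invisible(do.call(rbind, status))
}

#' Score results written by [benchRun()] into metric tables
#'
#' @param outDir the benchmark directory.
#' @param config configuration list.
#' @return A list with `records` (per-run AUROC/AUPRC, also written to
#'   `metrics.csv`) and the [aggregateMetrics()] `summary` (written to
#'   `summary.csv`).
#' @export
benchEvaluate <- function(outDir, config = benchConfig()) {
    manifest <- jsonlite::read_json(file.path(outDir, "manifest.json"))
    recs <- list()
    for (cell in manifest$cells) {
        d <- file.path(outDir, cell$id)
        truthFile <- file.path(d, "truth.tsv")
        if (!file.exists(truthFile)) stop("missing ground truth in ", d)
        truth <- binarizeTruth(readGroundTruth(truthFile))
        for (f in list.files(d, pattern = "_cells\\.tsv$")) {
            cells <- utils::read.delim(file.path(d, f))
            recs[[length(recs) + 1]] <- data.frame(
                method = cells$method[1], dataset = cell$topology,
                topology = cell$topology, da_ratio = cell$ratio,
                target_population = cell$target, seed = cell$seed,
                auroc = auroc(cells$score, truth,
                              config$evaluate$percentiles),
                auprc = auprc(cells$score, truth,
                              config$evaluate$percentiles),
                n_cells = nrow(cells))
        }
    }
    records <- do.call(rbind, recs)
    utils::write.csv(records, file.path(outDir, "metrics.csv"),
                     row.names = FALSE)
    agg <- aggregateMetrics(records)
    utils::write.csv(agg$summary, file.path(outDir, "summary.csv"),
                     row.names = FALSE)
    list(records = records, medians = agg$medians, summary = agg$summary)
}
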