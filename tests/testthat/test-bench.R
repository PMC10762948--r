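# a miniature configuration so the file-based drivers stay fast
miniConfig <- function() {
    cfg <- benchConfig()
    cfg$simulate$topologies <- list(cluster = list(nCells = 240,
                                                  nGenes = 40))
    cfg$simulate$p_da <- 0.95
    cfg$preprocess$n_components <- 10
    cfg$preprocess$k <- 8
    cfg$methods$louvain$resolution <- 1
    cfg$methods$milo$k <- 20
    cfg$methods$cydar$occupancy <- 30
    cfg$methods$daseq$kList <- c(10, 20)
    cfg$methods$daseq$nPermutations <- 5
    cfg$methods$cna$nPermutations <- 50
    cfg$seeds <- 1
    cfg
}

test_that("the simulate driver enumerates the grid and is guarded", {
    cfg <- miniConfig()
    out <- withr::local_tempdir()
    plan <- benchSimulate(out, cfg, targets = list(cluster = c("M1", "M2")),
                          dryRun = TRUE)
    expect_length(plan, 2)           # 1 topology x 2 targets x 1 x 1 x 1
    expect_length(list.files(out), 0)  # dry run writes nothing

    benchSimulate(out, cfg, targets = list(cluster = "M1"), seed = 4)
    expect_true(file.exists(file.path(out, "manifest.json")))
    expect_error(benchSimulate(out, cfg, targets = list(cluster = "M1")),
                 "force")

    # round trip: dataset and truth reload intact
    id <- list.dirs(out, recursive = FALSE)[1]
    sce <- readDataset(id)
    expect_equal(ncol(sce), 240)
    expect_length(unique(sce$sample), 6)
    tr <- readGroundTruth(file.path(id, "truth.tsv"))
    expect_equal(max(probC2(tr)), 0.95, tolerance = 1e-9)
})

test_that("the run driver is idempotent and rejects unknown methods", {
    cfg <- miniConfig()
    out <- withr::local_tempdir()
    benchSimulate(out, cfg, targets = list(cluster = "M1"), seed = 4)
    expect_error(benchRun(out, methods = "magic", cfg), "available")

    st1 <- suppressWarnings(benchRun(out, methods = "louvain", cfg,
                                     seed = 4))
    expect_equal(st1$status, "ok")
    st2 <- benchRun(out, methods = "louvain", cfg, seed = 4)
    expect_equal(st2$status, "cached")
})

test_that("the evaluate driver scores perfect and permuted fixtures", {
    cfg <- miniConfig()
    out <- withr::local_tempdir()
    benchSimulate(out, cfg, targets = list(cluster = "M1"), seed = 4)
    d <- list.dirs(out, recursive = FALSE)[1]
    tr <- readGroundTruth(file.path(d, "truth.tsv"))
    perfect <- data.frame(cell_id = tr@cellId, method = "oracle",
                          score = probC2(tr), direction = 1,
                          significant = TRUE, not_assessed = FALSE)
    write.table(perfect, file.path(d, "oracle_cells.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    set.seed(1)
    shuffled <- perfect
    shuffled$method <- "permuted"
    shuffled$score <- sample(perfect$score)
    write.table(shuffled, file.path(d, "permuted_cells.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)

    res <- benchEvaluate(out, cfg)
    expect_equal(res$records$auroc[res$records$method == "oracle"], 1,
                 tolerance = 1e-3)
    expect_equal(res$records$auroc[res$records$method == "permuted"], 0.5,
                 tolerance = 0.1)
    expect_true(file.exists(file.path(out, "metrics.csv")))
    expect_true(file.exists(file.path(out, "summary.csv")))
})

test_that("the in-memory grid is deterministic given the master seed", {
    cfg <- miniConfig()
    r1 <- runBenchmarkGrid(topologies = "cluster",
                          methods = c("meld", "louvain"),
                          daRatios = 0.95, seeds = 1,
                          targets = list(cluster = "M1"),
                          config = cfg, seed = 3)
    r2 <- runBenchmarkGrid(topologies = "cluster",
                          methods = c("meld", "louvain"),
                          daRatios = 0.95, seeds = 1,
                          targets = list(cluster = "M1"),
                          config = cfg, seed = 3)
    expect_identical(r1, r2)
})

test_that("the timing harness normalizes to the smallest size", {
    cfg <- miniConfig()
    tm <- suppressWarnings(benchTiming(sizes = 200,
                                       methods = c("meld", "louvain"),
                                       config = cfg, seed = 2))
    expect_equal(tm$relative_growth, rep(1, 2))
})
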