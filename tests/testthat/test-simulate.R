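test_that("topology simulation respects sizes, labels and determinism", {
    sce <- simulateTopology("cluster", nCells = 270, nGenes = 40, seed = 5)
    expect_equal(dim(sce), c(40L, 270L))
    expect_setequal(unique(sce$population), c("M1", "M2", "M3"))
    # M2 is the (unbalanced) majority population
    tab <- table(sce$population)
    expect_gt(tab[["M2"]], tab[["M1"]])
    expect_gt(tab[["M2"]], tab[["M3"]])

    lin <- simulateTopology("linear", nCells = 200, nGenes = 30, seed = 2)
    expect_setequal(unique(lin$population), paste0("P", 1:5))
    br <- simulateTopology("branch", nCells = 400, nGenes = 30, seed = 2)
    expect_true(all(br$population %in% c("S1", "S2", "A1", "A2",
                                         "B1", "B2")))

    again <- simulateTopology("cluster", nCells = 270, nGenes = 40, seed = 5)
    expect_identical(SummarizedExperiment::assay(sce, "counts"),
                     SummarizedExperiment::assay(again, "counts"))
    other <- simulateTopology("cluster", nCells = 270, nGenes = 40, seed = 6)
    expect_false(identical(SummarizedExperiment::assay(sce, "counts"),
                           SummarizedExperiment::assay(other, "counts")))

    expect_error(simulateTopology("cluster", nCells = 1, nGenes = 10),
                 "nCells")
    expect_error(simulateTopology("cluster", nCells = 100, nGenes = 10,
                                  populations = c(M1 = 10, M2 = 10)),
                 "sum")
})

test_that("DA planting maps the similarity ramp onto [0.5, pDA] exactly", {
    sce <- tinyCluster(seed = 3)
    tr <- plantDA(sce, "M1", 0.95)
    p <- probC2(tr)
    expect_equal(max(p), 0.95, tolerance = 1e-12)
    expect_equal(min(p), 0.5, tolerance = 1e-12)
    # rank preservation: probability is non-decreasing in w
    o <- order(tr@w)
    expect_true(all(diff(p[o]) >= 0))
    # target population carries the enrichment
    expect_gt(mean(p[sce$population == "M1"]),
              mean(p[sce$population != "M1"]))

    # null planting: no effect anywhere
    expect_true(all(probC2(plantDA(sce, "M1", 0.5)) == 0.5))
    # depletion planting mirrors onto [pDA, 0.5]
    dep <- probC2(plantDA(sce, "M1", 0.25))
    expect_equal(min(dep), 0.25, tolerance = 1e-12)
    expect_equal(max(dep), 0.5, tolerance = 1e-12)

    expect_error(plantDA(sce, "nope", 0.9), "population")
    expect_error(plantDA(sce, "M1", 1), "pDA")
})

test_that("ground-truth labels follow the threshold rule and partition", {
    sce <- tinyCluster(seed = 4)
    share <- prop.table(table(sce$population))[["M1"]]
    tr <- groundTruthLabels(plantDA(sce, "M1", 0.95), share)
    p <- probC2(tr)
    lab <- daLabels(tr)
    t <- tr@t
    expect_true(t > 0 && t < 0.5)
    expect_identical(lab, ifelse(p < t, "NegLFC",
                                 ifelse(p > 1 - t, "PosLFC", "NotDA")))
    # partition and, for enrichment plantings, no depleted label
    expect_true(all(lab %in% c("NegLFC", "PosLFC", "NotDA")))
    expect_false("NegLFC" %in% lab)
    # positives roughly track the target population share
    expect_equal(mean(lab == "PosLFC"), share, tolerance = 0.5 * share)
    # null dataset: everything NotDA
    trNull <- groundTruthLabels(plantDA(sce, "M1", 0.5), share)
    expect_true(all(daLabels(trNull) == "NotDA"))
    expect_error(groundTruthLabels(tr, 1.2), "targetProportion")
})

test_that("condition assignment is Bernoulli in the planted probability", {
    sce <- tinyCluster(seed = 6)
    n <- ncol(sce)
    forced <- new("GroundTruth", cellId = colnames(sce), w = rep(0, n),
                  probC2 = rep(1, n), pDA = 0.95, t = NA_real_,
                  label = character(0), targetPopulation = "M1")
    # degenerate Bernoulli: every cell lands in C2, so the C1 samples can
    # never be filled and the guarded resampling gives up
    expect_error(suppressWarnings(assignConditions(sce, forced, seed = 2,
                                                   retries = 3)),
                 "empty")

    big <- simulateTopology("linear", nCells = 10000, nGenes = 5, seed = 1)
    half <- new("GroundTruth", cellId = colnames(big), w = rep(0, 10000),
                probC2 = rep(0.5, 10000), pDA = 0.95, t = NA_real_,
                label = character(0), targetPopulation = "P1")
    out <- assignConditions(big, half, seed = 3)
    # binomial tail bound: 10,000 fair draws stay within 0.5 +/- 0.02
    expect_lt(abs(mean(out$condition == "C2") - 0.5), 0.02)
    expect_length(unique(out$sample), 6L)
    expect_identical(out$sample,
                     paste(out$condition, out$replicate, sep = "_"))
})

test_that("batch effects shift whole batches and vanish at sd zero", {
    fx <- tinyAssigned(seed = 7)
    sce <- fx$sce
    emb <- SingleCellExperiment::reducedDim(sce, "PCA")
    none <- addBatchEffects(sce, 0, seed = 1)
    expect_equal(SingleCellExperiment::reducedDim(none, "PCA"), emb)

    shifted <- addBatchEffects(sce, 1.5, seed = 1)
    delta <- SingleCellExperiment::reducedDim(shifted, "PCA") - emb
    # one shift vector per batch: identical rows within a batch
    for (b in unique(shifted$batch)) {
        rows <- delta[shifted$batch == b, , drop = FALSE]
        expect_equal(max(abs(sweep(rows, 2, rows[1, ]))), 0)
        # chi oracle: the sample sd of d iid N(0, 1.5) entries concentrates
        # around 1.5 (sd of the sd ~ 1.5 / sqrt(2(d-1)))
        expect_equal(sd(rows[1, ]), 1.5,
                     tolerance = 3 / sqrt(2 * (ncol(delta) - 1)))
    }
    # sample-level batches: batch constant within sample, both conditions
    # present in each batch
    expect_true(all(rowSums(table(shifted$sample, shifted$batch) > 0) == 1))
    expect_true(all(rowSums(table(shifted$batch,
                                  shifted$condition) > 0) == 2))
    expect_true("PCA_original" %in%
                    names(SingleCellExperiment::reducedDims(shifted)))
    expect_error(addBatchEffects(sce, -1), "non-negative")

    # cell-level assignment ignores samples
    byCell <- addBatchEffects(sce, 1, seed = 1, by = "cell")
    expect_gt(min(table(byCell$batch, byCell$sample)), 0)
})

test_that("population subsampling removes only the requested cells", {
    sce <- tinyCluster(seed = 8)
    n2 <- sum(sce$population == "M2")
    sub <- subsamplePopulation(sce, "M2", 50, seed = 1)
    expect_equal(sum(sub$population == "M2"), 50)
    expect_equal(sum(sub$population == "M1"),
                 sum(sce$population == "M1"))
    same <- subsamplePopulation(sce, "M2", n2, seed = 1)
    expect_equal(sort(colnames(same)), sort(colnames(sce)))
    gone <- subsamplePopulation(sce, "M2", 0, seed = 1)
    expect_false("M2" %in% gone$population)
    expect_error(plantDA(pcaEmbed(log1pNormalize(gone), 10), "M2", 0.9),
                 "population")
    expect_error(subsamplePopulation(sce, "M9", 10), "population")
})

test_that("scaling series yields independent per-size streams", {
    expect_length(simulateScalingSeries(integer(0)), 0L)
    one <- simulateScalingSeries(300, nGenes = 20, seed = 9)
    expect_length(one, 1L)
    expect_equal(ncol(one[[1]]), 300L)
    pair <- simulateScalingSeries(c(300, 400), nGenes = 20, seed = 9)
    expect_identical(SummarizedExperiment::assay(one[[1]], "counts"),
                     SummarizedExperiment::assay(pair[[1]], "counts"))
})
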