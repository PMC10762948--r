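test_that("the NAM follows the random-walk construction exactly", {
    # two-node graph: explicit matrix-power oracle
    emb <- matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE)
    g <- buildKnnGraph(emb, k = 1)
    sce <- twoBlobs(nPer = 60)[, 1:2]
    sce$sample <- c("C1_R1", "C2_R1")
    nm <- buildNAM(sce, g, steps = 1)
    expect_equal(as.matrix(nm@markov), matrix(0.5, 2, 2),
                 ignore_attr = TRUE)
    expect_equal(unname(nm@arrivals), rbind(c(0.5, 0.5), c(0.5, 0.5)))

    # steps = 0: arrivals count cells at their own positions
    sceB <- twoBlobs(nPer = 20)
    gB <- buildKnnGraph(SingleCellExperiment::reducedDim(sceB, "PCA"),
                        k = 3)
    nm0 <- buildNAM(sceB, gB, steps = 0)
    expect_equal(rowSums(nm0@arrivals),
                 as.numeric(table(sceB$sample)[nm0@samples]))

    # invariants on an arbitrary graph and walk length
    nm3 <- buildNAM(sceB, gB, steps = 3)
    expect_equal(max(abs(Matrix::colSums(nm3@markov) - 1)), 0,
                 tolerance = 1e-12)
    expect_equal(unname(rowSums(nam(nm3))), rep(1, nrow(nam(nm3))),
                 tolerance = 1e-12)
})

test_that("the NAM association test reacts to structure in y", {
    sce <- twoBlobs(nPer = 60)
    g <- buildKnnGraph(SingleCellExperiment::reducedDim(sce, "PCA"), k = 5)
    nm <- buildNAM(sce, g, steps = 3)
    y <- as.integer(substr(nm@samples, 1, 2) == "C2")

    res <- cnaTest(nm, y, maxK = 3, nPermutations = 200, seed = 1)
    # cloud B is C2-only: its cells carry positive smoothed correlation and
    # the largest magnitudes
    gam <- unitTable(res)$gamma
    expect_gt(median(gam[sce$population == "B"]),
              median(gam[sce$population == "A"]))
    # every pure-C2 cell co-varies positively with the C2 covariate; the
    # mixed cloud, relatively depleted of C2 mass, carries the opposite sign
    expect_true(all(gam[sce$population == "B"] > 0))
    expect_lt(median(gam[sce$population == "A"]), 0)

    # y orthogonal to every left singular vector: no association signal
    Qc <- scale(nam(nm), center = TRUE, scale = FALSE)
    sv <- svd(Qc)
    yOrth <- rep(1, length(y))  # constant y is orthogonal to centered U
    expect_error(cnaTest(nm, yOrth, maxK = 3), "constant")
    expect_error(cnaTest(nm, y, maxK = 10), "maxK")

    # permutation invariance in law: two independent null pools agree
    n1 <- cnaTest(nm, y, maxK = 3, nPermutations = 150, seed = 5)
    n2 <- cnaTest(nm, sample(y), maxK = 3, nPermutations = 150, seed = 9)
    ks <- suppressWarnings(ks.test(abs(unitTable(n1)$gamma),
                                   abs(unitTable(n2)$gamma)))
    expect_gt(ks$p.value, 1e-6)
})

test_that("graph KDE likelihoods respect support, symmetry and range", {
    sce <- twoBlobs(nPer = 60)
    g <- buildKnnGraph(SingleCellExperiment::reducedDim(sce, "PCA"), k = 5)
    res <- runMeld(sce, g, beta = 20)
    l <- unitTable(res)$likelihood_c2
    expect_true(all(l >= 0 & l <= 1))
    # the two clouds are disconnected at k = 5; the pure-C2 cloud has
    # likelihood 1 (filter preserves component support)
    expect_equal(unname(l[sce$population == "B"]), rep(1, 60),
                 tolerance = 1e-8)
    # identical C1/C2 indicators: force both conditions onto the same cells
    sceSym <- sce
    half <- rep(c("C1", "C2"), 60)
    sceSym$condition <- half
    sceSym$sample <- paste(half, sceSym$replicate, sep = "_")
    # cloud A mixes both conditions evenly at every position in expectation;
    # exact symmetry checked via condition relabeling instead:
    flip <- sce
    flip$condition <- ifelse(sce$condition == "C1", "C2", "C1")
    flip$sample <- paste(flip$condition, flip$replicate, sep = "_")
    resFlip <- runMeld(flip, g, beta = 20)
    expect_equal(unitTable(resFlip)$likelihood_c2, 1 - l, tolerance = 1e-8)
    expect_equal(cellScore(resFlip), cellScore(res), tolerance = 1e-8)
    expect_equal(cellDirection(resFlip), -cellDirection(res))
})

test_that("multiscale logistic regression saturates and is antisymmetric", {
    sce <- twoBlobs(nPer = 60)
    knn <- knnSearch(SingleCellExperiment::reducedDim(sce, "PCA"), 30)
    res <- runDAseq(sce, kList = c(10, 20, 30), nPermutations = 10,
                    seed = 1, knn = knn)
    m <- unitTable(res)$measure
    # cells in the pure-C2 cloud see only C2 neighbours at every scale
    expect_gt(min(m[sce$population == "B"]), 0.8)

    flip <- sce
    flip$condition <- ifelse(sce$condition == "C1", "C2", "C1")
    flip$sample <- paste(flip$condition, flip$replicate, sep = "_")
    resFlip <- runDAseq(flip, kList = c(10, 20, 30), nPermutations = 10,
                        seed = 1, knn = knn)
    expect_equal(unitTable(resFlip)$measure, -m, tolerance = 1e-4)
    expect_error(runDAseq(sce, kList = c(500)), "scales")
})

test_that("neighbourhood and hypersphere methods find a planted cluster", {
    fx <- tinyAssigned(nCells = 600, seed = 11, pDA = 0.95, target = "M1")
    sce <- fx$sce
    tb <- binarizeTruth(fx$truth)
    g <- buildKnnGraph(sce, k = 15)

    milo <- suppressWarnings(runMilo(sce, g, seed = 2))
    expect_equal(formals(runMilo)$sampleFraction, 0.1)
    expect_gt(auroc(cellScore(milo), tb), 0.8)
    expect_true(all(cellScore(milo)[notAssessed(milo)] == 0))

    cy <- suppressWarnings(runCydar(sce, graph = g, occupancy = 50,
                                    seed = 2))
    expect_gt(auroc(cellScore(cy), tb), 0.8)
    expect_true(all(unitTable(cy)$p_value >= 0 &
                        unitTable(cy)$p_value <= 1))
    expect_error(runCydar(sce, radius = -1, graph = g), "positive")

    lv <- suppressWarnings(runLouvain(sce, g, seed = 2))
    # piecewise-constant scores on clusters
    cl <- louvainClusters(g, 1, 2)
    expect_true(all(tapply(cellScore(lv), cl,
                           function(s) max(s) - min(s)) == 0))
    expect_gt(auroc(cellScore(lv), tb), 0.8)

    # resolution -> 0 gives a single cluster, still one testing unit
    lv0 <- suppressWarnings(runLouvain(sce, g, resolution = 1e-4,
                                       seed = 2))
    expect_lte(nrow(unitTable(lv0)), 3)

    # all cells in one condition: no contrast to test
    mono <- sce
    mono$condition <- "C2"
    mono$sample <- paste("C2", mono$replicate, sep = "_")
    expect_error(runCydar(mono, graph = g), "condition")
    expect_error(runMilo(mono, g), "condition")
})

test_that("flipping condition labels negates direction for every method", {
    fx <- tinyAssigned(nCells = 400, seed = 13, pDA = 0.95, target = "M3")
    sce <- fx$sce
    g <- buildKnnGraph(sce, k = 12)
    knn <- knnSearch(sce, 60)
    flip <- sce
    flip$condition <- ifelse(sce$condition == "C1", "C2", "C1")
    flip$sample <- paste(flip$condition, flip$replicate, sep = "_")

    runs <- list(
        milo = function(x) suppressWarnings(runMilo(x, g, seed = 3)),
        cydar = function(x) suppressWarnings(
            runCydar(x, graph = g, knn = knn, occupancy = 50, seed = 3)),
        louvain = function(x) suppressWarnings(runLouvain(
            x, g, seed = 3, clusters = louvainClusters(g, 1, 3))),
        cna = function(x) runCNA(x, g, nPermutations = 50, seed = 3),
        meld = function(x) runMeld(x, g, beta = 30),
        daseq = function(x) runDAseq(x, kList = c(20, 40), knn = knn,
                                     nPermutations = 5, seed = 3))
    for (nm in names(runs)) {
        a <- runs[[nm]](sce)
        b <- runs[[nm]](flip)
        expect_equal(cellScore(b), cellScore(a), tolerance = 1e-4,
                     label = paste(nm, "score"))
        keep <- cellScore(a) > 1e-6
        expect_equal(cellDirection(b)[keep], -cellDirection(a)[keep],
                     label = paste(nm, "direction"))
    }
})
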