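test_that("normalizations have their closed forms", {
    expect_equal(log1pNormalize(matrix(0, 2, 2)), matrix(0, 2, 2))
    expect_equal(log1pNormalize(exp(1) - 1), 1)
    expect_error(log1pNormalize(matrix(-1)), "non-negative")

    expect_equal(arcsinhTransform(0), 0)
    expect_equal(arcsinhTransform(5, cofactor = 5), log(1 + sqrt(2)))
    x <- rnorm(20)
    expect_equal(arcsinhTransform(-x), -arcsinhTransform(x))
    expect_error(arcsinhTransform(1, cofactor = 0), "positive")
})

test_that("PCA embedding is exact, ordered and sign-fixed", {
    set.seed(1)
    # degenerate geometry: points on a line load on one component
    line <- cbind(1:50, 2 * (1:50)) + 0
    emb <- pcaEmbed(line, 2)
    ve <- attr(emb, "varExplained")
    expect_gt(ve[1] / sum(ve), 0.999)

    X <- matrix(rnorm(100 * 20), 100, 20)
    emb <- pcaEmbed(X, 20)
    V <- attr(emb, "rotation")
    expect_equal(crossprod(V), diag(20), tolerance = 1e-8,
                 ignore_attr = TRUE)
    # full reconstruction equals the centered input
    Xc <- sweep(X, 2, colMeans(X))
    expect_equal(emb %*% t(V), Xc, tolerance = 1e-8,
                 ignore_attr = TRUE)
    # eigendecomposition oracle: explained variances match cov eigenvalues,
    # non-increasing
    ev <- eigen(cov(X), symmetric = TRUE)$values
    expect_equal(attr(emb, "varExplained"), ev[1:20], tolerance = 1e-8)
    expect_true(all(diff(attr(emb, "varExplained")) <= 1e-10))

    # row-permutation invariance (up to nothing: loadings sign-fixed)
    perm <- sample(100)
    emb2 <- pcaEmbed(X[perm, ], 5)
    expect_equal(attr(emb2, "rotation"), V[, 1:5], tolerance = 1e-6)
    expect_warning(pcaEmbed(cbind(1:10, (1:10) * 2), 2), "rank")
})

test_that("kNN graphs are symmetric union graphs with index tie-breaks", {
    two <- matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE)
    g <- buildKnnGraph(two, k = 1)
    expect_equal(Matrix::nnzero(adjacency(g)), 2)  # one undirected edge
    expect_true(Matrix::isSymmetric(adjacency(g)))

    # 3 collinear equidistant points: middle node keeps both edges after
    # union symmetrization (exhaustive distances: 1, 1, 2)
    three <- matrix(c(0, 0, 1, 0, 2, 0), 3, 2, byrow = TRUE)
    g3 <- buildKnnGraph(three, k = 1)
    A <- adjacency(g3)
    expect_equal(sum(A[2, ] != 0), 2)
    expect_true(all(A@x %in% c(0, 1)))           # binary kernel
    expect_true(all(Matrix::diag(A) == 0))
    # tie broken by index: endpoints equidistant from nothing here, but the
    # middle point's single nearest neighbour is the lower-index endpoint
    expect_equal(g3@knnIndex[2, 1], 1L)

    set.seed(2)
    emb <- matrix(rnorm(200), 50, 4)
    for (kern in c("gaussian", "alpha_decay")) {
        gk <- buildKnnGraph(emb, k = 5, kernel = kern)
        expect_true(Matrix::isSymmetric(adjacency(gk)))
        expect_true(all(adjacency(gk)@x >= 0))
        expect_true(all(adjacency(gk)@x <= 1))
    }
    expect_error(buildKnnGraph(emb, k = 0), "positive")
    expect_error(knnSearch(emb, 50), "smaller")

    # edge-list export round-trips the adjacency
    f <- withr::local_tempfile(fileext = ".tsv")
    writeCellGraph(g3, f)
    el <- read.delim(f)
    A3 <- Matrix::sparseMatrix(i = el$source, j = el$target, x = el$weight,
                               dims = dim(adjacency(g3)), symmetric = TRUE)
    expect_equal(as.matrix(A3), as.matrix(adjacency(g3)),
                 ignore_attr = TRUE)
})

test_that("well-separated clusters fall into separate graph components", {
    set.seed(3)
    emb <- rbind(matrix(rnorm(60, 0, 0.1), ncol = 2),
                 matrix(rnorm(60, 50, 0.1), ncol = 2),
                 cbind(rnorm(30, 0, 0.1), rnorm(30, 100, 0.1)))
    g <- buildKnnGraph(emb, k = 4)
    comp <- igraph::components(igraph::graph_from_adjacency_matrix(
        adjacency(g), mode = "undirected", weighted = TRUE))
    expect_gte(comp$no, 3)
})
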