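#' Log-normalize raw counts
#'
#' Elementwise natural log of (count + 1), the standard scRNA-seq
#' normalization used before PC embedding.
#'
#' @param x a non-negative count matrix, or a dataset with a `counts` assay
#'   (in which case a `logcounts` assay is added and the dataset returned).
#' @return The transformed matrix, or the dataset with `logcounts`.
#' @export
log1pNormalize <- function(x) {
    if (is(x, "SummarizedExperiment")) {
        m <- SummarizedExperiment::assay(x, "counts")
        if (any(m < 0)) stop("counts must be non-negative")
        SummarizedExperiment::assay(x, "logcounts") <- log1p(m)
        return(x)
    }
    if (any(x < 0)) stop("counts must be non-negative")
    log1p(x)
}

#' Arcsinh transform with a cofactor
#'
#' `asinh(x / cofactor)`, the standard mass-cytometry (CyTOF) normalization;
#' the default cofactor is 5.
#'
#' @param x numeric matrix or vector.
#' @param cofactor positive scale divisor.
#' @return The transformed values.
#' @export
arcsinhTransform <- function(x, cofactor = 5) {
    if (cofactor <= 0) stop("cofactor must be positive")
    asinh(x / cofactor)
}

# centered exact PCA of a cells x genes matrix via the gene-space
# eigendecomposition; sign fixed so each loading's largest-magnitude entry is
# positive.
.pca <- function(X, nComponents) {
    center <- colMeans(X)
    Xc <- sweep(X, 2, center)
    ev <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)
    lambda <- pmax(ev$values, 0)
    rank <- sum(lambda > lambda[1] * 1e-12)
    if (nComponents > rank) {
        warning("requested ", nComponents, " components but rank is ", rank,
                "; truncating")
        nComponents <- rank
    }
    V <- ev$vectors[, seq_len(nComponents), drop = FALSE]
    flip <- apply(V, 2, function(v) sign(v[which.max(abs(v))]))
    V <- sweep(V, 2, flip, `*`)
    scores <- Xc %*% V
    colnames(scores) <- colnames(V) <- paste0("PC", seq_len(nComponents))
    list(embedding = scores, rotation = V, center = center,
         varExplained = lambda[seq_len(nComponents)], totalVar = sum(lambda))
}

#' Principal-component embedding
#'
#' Centered, exact PCA (no gene scaling, matching common scRNA-seq practice)
#' of the normalized expression matrix; the top `nComponents` scores are
#' stored as the `"PCA"` reduced dimension with the loadings, centering
#' vector and explained variances as attributes. The deterministic sign
#' convention makes each loading's largest-magnitude entry positive.
#'
#' @param x a dataset with a `logcounts` assay (see [log1pNormalize()]), or a
#'   cells x features matrix.
#' @param nComponents number of components (default 50), at most
#'   `min(cells, genes)`.
#' @param assay assay to embed when `x` is a dataset.
#' @return The dataset with `reducedDim(x, "PCA")` set, or (matrix input) the
#'   scores matrix with attributes `rotation`, `center`, `varExplained`.
#' @export
pcaEmbed <- function(x, nComponents = 50, assay = "logcounts") {
    if (is(x, "SummarizedExperiment")) {
        X <- t(as.matrix(SummarizedExperiment::assay(x, assay)))
        p <- .pca(X, min(nComponents, dim(X)))
        emb <- p$embedding
        attr(emb, "rotation") <- p$rotation
        attr(emb, "center") <- p$center
        attr(emb, "varExplained") <- p$varExplained
        SingleCellExperiment::reducedDim(x, "PCA") <- emb
        return(x)
    }
    p <- .pca(x, min(nComponents, dim(x)))
    emb <- p$embedding
    attr(emb, "rotation") <- p$rotation
    attr(emb, "center") <- p$center
    attr(emb, "varExplained") <- p$varExplained
    emb
}

#' Exact k-nearest neighbours by Euclidean distance
#'
#' Brute-force search (BLAS-backed, computed in row blocks); ties are broken
#' by cell index for reproducibility.
#'
#' @param embedding cells x d numeric matrix, or a dataset with a `"PCA"`
#'   reduced dimension.
#' @param k neighbours per cell, `0 < k < n`.
#' @return A list with integer `index` (n x k, 1-based, nearest first) and
#'   numeric `distance` (n x k).
#' @export
knnSearch <- function(embedding, k) {
    emb <- .getEmbedding(embedding)
    if (k <= 0) stop("k must be positive")
    if (k >= nrow(emb)) stop("k must be smaller than the number of cells")
    .knn_brute(emb, as.integer(k))
}

#' Build a weighted kNN cell graph
#'
#' Directed kNN edges by Euclidean distance in the embedding, weighted by the
#' chosen kernel and symmetrized by union (elementwise maximum of the
#' adjacency and its transpose), which keeps small datasets connected.
#' Kernels:
#' \describe{
#'   \item{binary}{all edges weight 1.}
#'   \item{gaussian}{`exp(-d^2 / h^2)` with global bandwidth `h` = median
#'     distance to the k-th neighbour.}
#'   \item{alpha_decay}{`exp(-(d / h_i)^alpha)` with `alpha = 10` and
#'     adaptive bandwidth `h_i` = distance to the `ceiling(k/3)`-th neighbour
#'     of the source cell.}
#' }
#'
#' @param x embedding matrix or a dataset with a `"PCA"` reduced dimension.
#' @param k neighbours per cell (default 30).
#' @param kernel edge-weight kernel.
#' @param knn optional precomputed [knnSearch()] result (with `>= k`
#'   columns), to share neighbour searches across graphs.
#' @return A \linkS4class{CellGraph}.
#' @export
buildKnnGraph <- function(x, k = 30, kernel = c("binary", "gaussian",
                                                "alpha_decay"),
                          knn = NULL) {
    kernel <- match.arg(kernel)
    if (k <= 0) stop("k must be positive")
    if (is.null(knn)) knn <- knnSearch(x, k)
    if (ncol(knn$index) < k) stop("precomputed knn has fewer than k columns")
    idx <- knn$index[, seq_len(k), drop = FALSE]
    d <- knn$distance[, seq_len(k), drop = FALSE]
    n <- nrow(idx)
    w <- switch(kernel,
        binary = rep(1, length(idx)),
        gaussian = {
            h <- stats::median(d[, k])
            as.vector(exp(-(d / h)^2))
        },
        alpha_decay = {
            h <- pmax(d[, ceiling(k / 3)], .Machine$double.eps)
            as.vector(exp(-(d / h)^10))
        })
    A <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(idx),
                              x = as.numeric(w), dims = c(n, n))
    # union symmetrization: elementwise max, kept sparse
    A <- (A + Matrix::t(A) + abs(A - Matrix::t(A))) / 2
    A <- Matrix::drop0(A)
    new("CellGraph", adjacency = A, k = as.integer(k), kernel = kernel,
        knnIndex = idx, knnDist = d)
}
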