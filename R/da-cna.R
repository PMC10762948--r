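#' Build the random-walk neighbourhood abundance matrix (NAM)
#'
#' Forms the column-stochastic random-walk matrix with self-loops,
#' `M = (I + A) / (1 + colSums(A))` (column-normalized, so each column sums
#' to one; the `+1` self-loop guards isolated nodes), walks `steps` steps
#' from every cell of every sample, and records the per-sample arrival mass
#' at each cell. Row-normalizing the arrival matrix gives the NAM `Q`, whose
#' entry `(n, m)` is the relative abundance of sample `n` in the
#' neighbourhood of cell `m`.
#'
#' @param x dataset with assigned samples.
#' @param graph \linkS4class{CellGraph}.
#' @param steps random-walk length (>= 0; 0 counts cells at their own
#'   positions).
#' @param groups optional per-cell grouping overriding `x$sample` (used for
#'   sample-by-batch pseudo-samples).
#' @return A \linkS4class{NamModel}.
#' @export
buildNAM <- function(x, graph, steps = 3, groups = NULL) {
    if (steps < 0) stop("steps must be non-negative")
    A <- graph@adjacency
    n <- nrow(A)
    markov <- (Matrix::Diagonal(n) + A) %*%
        Matrix::Diagonal(x = 1 / (1 + Matrix::colSums(A)))
    if (is.null(groups)) {
        .checkMultiSample(x)
        groups <- x$sample
    }
    lev <- sort(unique(groups))
    S <- Matrix::sparseMatrix(i = match(groups, lev), j = seq_len(n),
                              x = 1, dims = c(length(lev), n))
    R <- S
    for (i in seq_len(steps)) R <- R %*% markov
    R <- as.matrix(R)
    Q <- R / rowSums(R)
    new("NamModel", markov = markov, steps = as.integer(steps),
        arrivals = R, nam = Q, samples = lev)
}

# F-test of y on the first k left singular vectors (y centered, U columns
# orthonormal and mean-zero after column-centering Q)
.cnaFit <- function(sv, yc, k, df2) {
    beta <- crossprod(sv$u[, seq_len(k), drop = FALSE], yc)
    r2 <- sum(beta^2) / sum(yc^2)
    f <- (r2 / k) / ((1 - r2) / df2)
    list(beta = beta,
         p = stats::pf(f, k, df2, lower.tail = FALSE))
}

.cnaGamma <- function(sv, yc, maxK, S) {
    ps <- vapply(seq_len(maxK), function(k)
        .cnaFit(sv, yc, k, S - 1 - k)$p, numeric(1))
    kStar <- which.min(ps)
    beta <- .cnaFit(sv, yc, kStar, S - 1 - kStar)$beta
    gamma <- sv$v[, seq_len(kStar), drop = FALSE] %*%
        (sv$d[seq_len(kStar)] * beta)
    list(gamma = as.vector(gamma), kStar = kStar, p = ps)
}

#' Association test on the NAM (Cna-style)
#'
#' Column-centers the NAM and takes its SVD; for each candidate number of
#' components `k` the sample covariate `y` is regressed on the first `k`
#' left singular vectors and tested with a multivariate F-test; the `k` with
#' the smallest p-value is selected. The per-cell smoothed correlation is
#' `gamma = V D beta` at the selected `k`. Significance is assessed against
#' a pooled null of `|gamma|` values obtained by re-running the fit
#' (including component selection) under permutations of `y`; the per-cell
#' FDR is the monotone tail-ratio estimate. The DA score is `|gamma|` and
#' the direction its sign.
#'
#' @param namModel a \linkS4class{NamModel}.
#' @param y per-sample covariate (numeric, or a two-level factor; C2-like
#'   second level coded 1).
#' @param maxK largest number of components (default
#'   `min(10, samples - 2)`).
#' @param nPermutations permutations for the null (default 1000).
#' @param fdr FDR threshold for the significance calls.
#' @param seed integer seed (permutation stream).
#' @param batch optional per-sample batch factor; `y` and the NAM are
#'   residualized on it before testing.
#' @return A \linkS4class{DAResult}; the per-k F-test p-values and selected
#'   `k` are in `hyperparams`.
#' @export
cnaTest <- function(namModel, y, maxK = NULL, nPermutations = 1000,
                    fdr = 0.1, seed = 1, batch = NULL) {
    Q <- namModel@nam
    S <- nrow(Q)
    if (S < 4) stop("at least 4 samples are required")
    if (is.factor(y) || is.character(y))
        y <- as.integer(factor(y)) - 1
    y <- as.numeric(y)
    if (length(y) != S) stop("y must have one entry per sample")
    if (stats::sd(y) == 0) stop("y is constant")
    if (is.null(maxK)) maxK <- min(10, S - 2)
    if (maxK < 1 || maxK > S - 2) stop("maxK must lie in [1, samples - 2]")

    Qc <- scale(Q, center = TRUE, scale = FALSE)
    yc <- y - mean(y)
    if (!is.null(batch)) {
        B <- stats::model.matrix(~factor(batch))
        H <- B %*% solve(crossprod(B), t(B))
        yc <- as.vector(yc - H %*% yc)
        if (stats::sd(yc) == 0)
            stop("y is confounded with batch (constant after residualization)")
        Qc <- Qc - H %*% Qc
    }
    sv <- svd(Qc)
    obs <- .cnaGamma(sv, yc, maxK, S)

    set.seed(childSeed(seed, "cna"))
    thr <- sort(abs(obs$gamma))
    nullGE <- numeric(length(thr))  # accumulated null tail counts
    for (b in seq_len(nPermutations)) {
        gp <- sort(abs(.cnaGamma(sv, sample(yc), maxK, S)$gamma))
        nullGE <- nullGE + (length(gp) - findInterval(thr, gp,
                                                      left.open = TRUE))
    }
    obsGE <- length(thr) - seq_along(thr) + 1
    fdrSorted <- pmin((nullGE / max(nPermutations, 1)) / obsGE, 1)
    # q-value convention: a cell's FDR is the best achievable over rejection
    # regions that still contain it (thresholds at or below its |gamma|)
    fdrSorted <- cummin(fdrSorted)
    cellFdr <- fdrSorted[match(abs(obs$gamma), thr)]
    n <- length(obs$gamma)
    new("DAResult", method = "cna", cellScore = abs(obs$gamma),
        cellDirection = sign(obs$gamma),
        significant = if (nPermutations > 0) cellFdr <= fdr
                      else rep(FALSE, n),
        notAssessed = rep(FALSE, n),
        unitTable = data.frame(cell = seq_len(n), gamma = obs$gamma,
                               fdr = cellFdr),
        hyperparams = list(kStar = obs$kStar, pByK = obs$p, maxK = maxK,
                           steps = namModel@steps,
                           nPermutations = nPermutations, fdr = fdr,
                           seed = seed))
}

#' Run the full Cna-style pipeline
#'
#' Convenience wrapper: builds the NAM from the graph (using sample-by-batch
#' pseudo-samples when `batch = TRUE`) and applies [cnaTest()] with the
#' condition as covariate.
#'
#' @inheritParams buildNAM
#' @inheritParams cnaTest
#' @param batch logical; residualize on the batch factor via pseudo-samples.
#' @return A \linkS4class{DAResult}.
#' @export
runCNA <- function(x, graph, steps = 3, maxK = NULL, nPermutations = 1000,
                   fdr = 0.1, batch = FALSE, seed = 1) {
    .checkMultiSample(x)
    if (batch && is.null(x$batch))
        stop("batch covariate requested but the dataset has no batch labels")
    groups <- if (batch) paste(x$sample, x$batch, sep = ".") else x$sample
    nm <- buildNAM(x, graph, steps, groups = groups)
    cond <- substr(nm@samples, 1, 2)
    bt <- if (batch) sub(".*\\.", "", nm@samples) else NULL
    cnaTest(nm, y = as.integer(cond == "C2"), maxK = maxK,
            nPermutations = nPermutations, fdr = fdr, seed = seed,
            batch = bt)
}
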