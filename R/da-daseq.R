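#' Multiscale logistic-regression DA testing (DA-seq-style)
#'
#' For every cell and every scale `k` in `kList`, the feature
#' `(n_C2 - n_C1) / k` summarizes the condition balance among the cell's k
#' nearest neighbours. A ridge-regularized logistic regression predicts each
#' cell's condition from its multiscale feature vector; the DA measure is
#' `2 * fitted_probability - 1`. Permuting the condition labels
#' `nPermutations` times and refitting yields the highest and lowest DA
#' measures expected under the null; cells outside `[min_null, max_null]`
#' are significant. The DA score is `|measure|` and the direction its sign.
#'
#' @param x dataset with assigned samples and a `"PCA"` embedding.
#' @param kList increasing neighbourhood scales (default 50 to 500 by 50);
#'   scales of at least the cell count are dropped.
#' @param nPermutations label permutations for the null thresholds.
#' @param seed integer seed (permutation stream).
#' @param knn optional precomputed [knnSearch()] result with at least
#'   `max(kList)` neighbours.
#' @param lambda ridge penalty (default 1e-3).
#' @return A \linkS4class{DAResult}; null thresholds are recorded in
#'   `hyperparams`.
#' @export
runDAseq <- function(x, kList = seq(50, 500, by = 50), nPermutations = 50,
                     seed = 1, knn = NULL, lambda = 1e-3) {
    .assertCondition(x$condition)
    n <- ncol(x)
    kList <- as.integer(kList[kList < n])
    if (!length(kList)) stop("no usable scales below the cell count")
    if (is.unsorted(kList, strictly = TRUE)) stop("kList must be increasing")
    if (is.null(knn)) knn <- knnSearch(.getEmbedding(x), max(kList))
    if (ncol(knn$index) < max(kList))
        stop("precomputed knn has fewer than max(kList) neighbours")
    nnIdx <- knn$index
    y <- .cond01(x$condition)

    measure <- function(y01) {
        cnt <- .label_counts_at_scales(nnIdx, as.integer(y01), kList)
        feat <- sweep(2 * cnt, 2, kList, `/`) - 1  # (nC2 - nC1) / k
        fit <- glmnet::glmnet(feat, factor(y01, levels = c(0, 1)),
                              family = "binomial", alpha = 0,
                              lambda = lambda, standardize = FALSE)
        p <- as.vector(stats::predict(fit, feat, type = "response"))
        2 * p - 1
    }

    obs <- measure(y)
    set.seed(childSeed(seed, "daseq"))
    hi <- -Inf; lo <- Inf
    for (b in seq_len(nPermutations)) {
        m <- measure(sample(y))
        hi <- max(hi, max(m)); lo <- min(lo, min(m))
    }
    sig <- if (nPermutations > 0) obs > hi | obs < lo else rep(FALSE, n)
    new("DAResult", method = "daseq", cellScore = abs(obs),
        cellDirection = sign(obs), significant = sig,
        notAssessed = rep(FALSE, n),
        unitTable = data.frame(cell = seq_len(n), measure = obs),
        hyperparams = list(kList = kList, nPermutations = nPermutations,
                           lambda = lambda, nullMax = hi, nullMin = lo,
                           seed = seed))
}
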