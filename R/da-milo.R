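#' Neighbourhood-based DA testing (Milo-style)
#'
#' A fraction of cells is sampled as index cells; each index cell's testing
#' unit is its first-order neighbourhood in the (union-symmetrized) kNN
#' graph, including itself. Per-sample counts in each
#' neighbourhood are tested with a negative-binomial GLM ([nbGlmTest()]) and
#' multiplicity is controlled by the spatial FDR ([spatialFDR()]) with
#' density weights equal to the reciprocal of the index cell's distance to
#' its k-th neighbour. Because neighbourhoods overlap, each cell aggregates
#' the signed values `sign(logFC) * (1 - adjusted)` over the neighbourhoods
#' that contain it, normalized by how many contain it (otherwise a cell's
#' score mostly reflects its membership count rather than the strength of
#' the evidence); the DA score is the magnitude of that signed mean and the
#' direction its sign. Cells in no sampled neighbourhood are flagged not
#' assessed.
#'
#' @param x dataset with assigned samples.
#' @param graph \linkS4class{CellGraph} built on the current embedding.
#' @param sampleFraction fraction of cells used as index cells (default 0.1).
#' @param alpha spatial FDR level.
#' @param batch logical; model the batch covariate.
#' @param seed integer seed for index-cell sampling.
#' @return A \linkS4class{DAResult}.
#' @export
runMilo <- function(x, graph, sampleFraction = 0.1, alpha = 0.1,
                    batch = FALSE, seed = 1) {
    .assertCondition(x$condition)
    n <- nrow(graph@knnIndex)
    nIdx <- floor(sampleFraction * n)
    if (nIdx < 1) stop("sampleFraction yields no index cells")
    set.seed(childSeed(seed, "milo"))
    idx <- sort(sample.int(n, nIdx))
    A <- graph@adjacency
    members <- lapply(idx, function(i) {
        nb <- A@i[(A@p[i] + 1):A@p[i + 1]] + 1L  # column i neighbours
        c(i, nb)
    })
    des <- .countingDesign(x, batch)
    counts <- .unitCounts(members, des$colIdx, length(des$levels))
    fit <- nbGlmTest(counts, des$condition, des$batch)
    w <- 1 / pmax(graph@knnDist[idx, ncol(graph@knnDist)],
                  .Machine$double.eps)
    sf <- spatialFDR(fit$p_value, w, alpha)

    score <- rep(0, n)
    sig <- rep(FALSE, n)
    seen <- rep(FALSE, n)
    nIn <- rep(0L, n)
    for (u in seq_along(members)) {
        m <- members[[u]]
        seen[m] <- TRUE
        nIn[m] <- nIn[m] + 1L
        score[m] <- score[m] + sign(fit$logFC[u]) * (1 - sf$adjusted[u])
        if (sf$significant[u]) sig[m] <- TRUE
    }
    score <- ifelse(nIn > 0, score / pmax(nIn, 1L), 0)
    unit <- data.frame(index_cell = idx, n_cells = lengths(members),
                       logFC = fit$logFC, p_value = fit$p_value,
                       spatial_fdr = sf$adjusted,
                       significant = sf$significant)
    new("DAResult", method = "milo", cellScore = abs(score),
        cellDirection = sign(score), significant = sig, notAssessed = !seen,
        unitTable = unit,
        hyperparams = list(sampleFraction = sampleFraction, alpha = alpha,
                           k = graph@k, batch = batch, seed = seed))
}
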