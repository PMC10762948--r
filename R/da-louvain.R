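#' Cluster-level DA testing (Louvain-style)
#'
#' Partitions the cell graph with Louvain modularity clustering, counts cells
#' per sample in each cluster, tests each cluster with a negative-binomial
#' GLM ([nbGlmTest()]) and corrects across clusters with standard
#' Benjamini-Hochberg (clusters partition the cells and have no natural
#' volume weight, so no spatial weighting is applied). All cells of a
#' cluster share the cluster's score `1 - adjusted p` and the sign of its
#' log fold change, so per-cell scores are piecewise constant on clusters.
#'
#' @param x dataset with assigned samples.
#' @param graph \linkS4class{CellGraph}.
#' @param resolution Louvain resolution (default 1; smaller values give
#'   coarser partitions).
#' @param alpha BH FDR level for the significance calls.
#' @param batch logical; model the batch covariate.
#' @param seed integer seed (Louvain refinement order).
#' @param clusters optional precomputed integer membership vector, to share
#'   one clustering across runs on the same graph.
#' @return A \linkS4class{DAResult}.
#' @export
runLouvain <- function(x, graph, resolution = 1, alpha = 0.1, batch = FALSE,
                       seed = 1, clusters = NULL) {
    .assertCondition(x$condition)
    if (is.null(clusters)) clusters <- louvainClusters(graph, resolution,
                                                      seed)
    nCl <- max(clusters)
    members <- split(seq_along(clusters), clusters)
    des <- .countingDesign(x, batch)
    counts <- .unitCounts(members, des$colIdx, length(des$levels))
    fit <- nbGlmTest(counts, des$condition, des$batch)
    adj <- stats::p.adjust(fit$p_value, method = "BH")
    sig <- adj <= alpha & !fit$not_assessed
    score <- (1 - adj)[clusters]
    dir <- sign(fit$logFC)[clusters]
    unit <- data.frame(cluster = seq_len(nCl), n_cells = lengths(members),
                       logFC = fit$logFC, p_value = fit$p_value,
                       fdr = adj, significant = sig)
    new("DAResult", method = "louvain", cellScore = score,
        cellDirection = dir, significant = sig[clusters],
        notAssessed = fit$not_assessed[clusters], unitTable = unit,
        hyperparams = list(resolution = resolution, alpha = alpha,
                           batch = batch, seed = seed,
                           nClusters = nCl))
}

#' Louvain clustering of a cell graph
#'
#' @inheritParams runLouvain
#' @return Integer cluster membership per cell.
#' @export
louvainClusters <- function(graph, resolution = 1, seed = 1) {
    g <- igraph::graph_from_adjacency_matrix(graph@adjacency,
                                             mode = "undirected",
                                             weighted = TRUE)
    set.seed(childSeed(seed, "louvain"))
    as.integer(igraph::cluster_louvain(g, resolution = resolution)$membership)
}
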