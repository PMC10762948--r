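#' Hypersphere-based DA testing (Cydar-style)
#'
#' Random cells are taken as hypersphere centres in PC space; every cell
#' within `radius` of a centre belongs to that hypersphere. Per-sample cell
#' counts in each hypersphere are tested with a negative-binomial GLM
#' ([nbGlmTest()]) and multiplicity is controlled by the spatial FDR
#' ([spatialFDR()]) with density weights equal to the reciprocal of the
#' number of centres within `radius` of each centre. Each cell's DA score is
#' the largest `1 - adjusted` value over its containing hyperspheres, with
#' the direction of that hypersphere's log fold change.
#'
#' @param x dataset with `"PCA"` embedding and assigned samples.
#' @param radius hypersphere radius; default the median distance to the
#'   `occupancy`-th nearest neighbour, giving median hypersphere occupancies
#'   near `occupancy`.
#' @param occupancy target median hypersphere occupancy used to calibrate
#'   the default radius (default 100). A fixed multiple of a typical
#'   kNN distance is not usable here: in a 50-dimensional embedding,
#'   distance concentration makes occupancy explode within a small factor
#'   of the median neighbour distance.
#' @param knn optional precomputed [knnSearch()] result with at least
#'   `occupancy` columns, reused for radius calibration.
#' @param centerFraction fraction of cells sampled as centres.
#' @param alpha spatial FDR level.
#' @param batch logical; model the batch covariate (see [nbGlmTest()]).
#' @param seed integer seed for centre sampling.
#' @param graph optional \linkS4class{CellGraph}; reused for the default
#'   radius so no extra neighbour search is needed.
#' @return A \linkS4class{DAResult}.
#' @export
runCydar <- function(x, radius = NULL, occupancy = 100,
                     centerFraction = 0.1, alpha = 0.1, batch = FALSE,
                     seed = 1, graph = NULL, knn = NULL) {
    emb <- .getEmbedding(x)
    n <- nrow(emb)
    .assertCondition(x$condition)
    if (is.null(radius)) {
        occ <- min(occupancy, n - 1)
        kd <- if (!is.null(knn) && ncol(knn$distance) >= occ) knn$distance
              else if (!is.null(graph) && ncol(graph@knnDist) >= occ)
                  graph@knnDist
              else knnSearch(emb, occ)$distance
        radius <- stats::median(kd[, occ])
    }
    if (radius <= 0) stop("radius must be positive")
    set.seed(childSeed(seed, "cydar"))
    centers <- sort(sample.int(n, max(1, ceiling(centerFraction * n))))
    members <- .radius_members(emb[centers, , drop = FALSE], emb, radius)
    des <- .countingDesign(x, batch)
    counts <- .unitCounts(members, des$colIdx, length(des$levels))
    fit <- nbGlmTest(counts, des$condition, des$batch)
    dens <- lengths(.radius_members(emb[centers, , drop = FALSE],
                                    emb[centers, , drop = FALSE], radius))
    sf <- spatialFDR(fit$p_value, 1 / dens, alpha)
    agg <- .bestUnitPerCell(members, sf$adjusted, fit$logFC, sf$significant, n)
    unit <- data.frame(center = centers, n_cells = lengths(members),
                       logFC = fit$logFC, p_value = fit$p_value,
                       spatial_fdr = sf$adjusted,
                       significant = sf$significant)
    new("DAResult", method = "cydar", cellScore = agg$score,
        cellDirection = agg$direction, significant = agg$significant,
        notAssessed = agg$notAssessed, unitTable = unit,
        hyperparams = list(radius = radius, occupancy = occupancy,
                           centerFraction = centerFraction,
                           alpha = alpha, batch = batch, seed = seed))
}
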