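#' Simulate a single-cell count dataset with known topology
#'
#' Draws a latent structure of the requested kind (a 1-D path, a bifurcating
#' path, or discrete clusters), maps it through per-gene response curves to
#' negative-binomial count means, and samples counts. Population labels are
#' attached per cell; conditions and samples are assigned later by
#' [assignConditions()] once a DA effect has been planted.
#'
#' The latent generative models are stand-ins for trajectory simulators:
#' \describe{
#'   \item{linear}{latent time `u ~ Uniform(0,1)`; each gene carries a
#'     locally-activated program, a Gaussian bump in latent time with random
#'     centre and width, so cells that are close in latent time share many
#'     active genes (the property that makes kNN neighbourhoods follow the
#'     trajectory); populations are 5 equal latent-time segments `P1..P5`.}
#'   \item{branch}{a root segment (`u < 0.4`) bifurcating into branches A and
#'     B; besides the shared program, each branch activates its own
#'     bump-shaped gene programs past the branch point; populations are
#'     segments `S1, S2` on the root and `A1, A2` / `B1, B2` on the
#'     branches.}
#'   \item{cluster}{per-population gene-level effects drawn from a Gaussian;
#'     default populations `M1/M2/M3` are unbalanced with M2 holding roughly
#'     half the cells.}
#' }
#' Gene means are `lib * softplus(eta)` with `lib = 3`, giving realistic
#' per-cell totals around 1500 counts over 500 genes.
#'
#' @param kind `"linear"`, `"branch"` or `"cluster"`.
#' @param nCells,nGenes dataset dimensions (counts are genes x cells).
#' @param populations for `kind = "cluster"`, a named integer vector of
#'   population sizes summing to `nCells`; ignored for trajectories. Default
#'   `NULL` uses the built-in populations described above.
#' @param dispersion common NB dispersion (variance `mu + dispersion * mu^2`).
#' @param seed integer master seed; counts are reproducible given the seed.
#' @return A [SingleCellExperiment::SingleCellExperiment] with a `counts`
#'   assay, `colData` columns `cell_id` and `population` (plus latent
#'   coordinates), and the generative configuration in `metadata(x)$topology`.
#' @examples
#' sce <- simulateTopology("cluster", nCells = 300, nGenes = 50, seed = 1)
#' table(sce$population)
#' @export
simulateTopology <- function(kind = c("linear", "branch", "cluster"),
                             nCells, nGenes, populations = NULL,
                             dispersion = 0.5, seed = 1) {
    kind <- match.arg(kind)
    if (nCells < 2) stop("nCells must be at least 2")
    if (nGenes < 1) stop("nGenes must be at least 1")
    set.seed(childSeed(seed, paste0("topology.", kind)))
    size <- 1 / dispersion

    if (kind == "cluster") {
        if (is.null(populations)) {
            base <- c(M1 = 13, M2 = 28, M3 = 13) / 54
            populations <- round(base * nCells)
            populations[1] <- nCells - sum(populations[-1])
        }
        if (is.null(names(populations)) || any(populations < 1))
            stop("populations must be a named vector of positive sizes")
        if (sum(populations) != nCells)
            stop("population sizes must sum to nCells")
        pop <- rep(names(populations), populations)
        a <- stats::rnorm(nGenes, 0.5, 1)
        delta <- matrix(stats::rnorm(nGenes * length(populations), 0, 1),
                        nGenes, length(populations),
                        dimnames = list(NULL, names(populations)))
        mu <- softplus(a + delta[, pop, drop = FALSE])
        latent <- data.frame(latent_time = NA_real_)
    } else {
        u <- stats::runif(nCells)
        a <- stats::rnorm(nGenes, 0.5, 1)
        # locally-activated gene programs: amplitude, centre and width of a
        # Gaussian bump in latent time, per gene
        b <- stats::rnorm(nGenes, 0, 4)
        m <- stats::runif(nGenes)
        sw <- stats::runif(nGenes, 0.05, 0.15)
        bump <- function(mm, ss) exp(-outer(mm, u, "-")^2 / (2 * ss^2))
        eta <- outer(a, rep(1, nCells)) + b * bump(m, sw)
        if (kind == "linear") {
            pop <- paste0("P", findInterval(u, seq(0.2, 0.8, by = 0.2)) + 1)
        } else {
            branch <- ifelse(u < 0.4, "root",
                             sample(c("A", "B"), nCells, replace = TRUE))
            bA <- stats::rnorm(nGenes, 0, 4)
            bB <- stats::rnorm(nGenes, 0, 4)
            mBr <- stats::runif(nGenes, 0.45, 1)
            swBr <- stats::runif(nGenes, 0.05, 0.15)
            eta <- eta + bA * bump(mBr, swBr) *
                rep(branch == "A", each = nGenes)
            eta <- eta + bB * bump(mBr, swBr) *
                rep(branch == "B", each = nGenes)
            pop <- ifelse(branch == "root",
                          ifelse(u < 0.2, "S1", "S2"),
                          paste0(branch, ifelse(u < 0.7, "1", "2")))
        }
        mu <- softplus(eta)
        latent <- data.frame(latent_time = u)
        if (kind == "branch") latent$branch <- branch
    }

    counts <- matrix(stats::rnbinom(nGenes * nCells, mu = 3 * mu,
                                    size = size),
                     nGenes, nCells)
    rownames(counts) <- sprintf("gene_%d", seq_len(nGenes))
    colnames(counts) <- sprintf("cell_%d", seq_len(nCells))
    cd <- S4Vectors::DataFrame(cell_id = colnames(counts), population = pop,
                               latent)
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts), colData = cd)
    S4Vectors::metadata(sce)$topology <- list(kind = kind, nCells = nCells,
        nGenes = nGenes, dispersion = dispersion, seed = seed)
    sce
}

#' Plant a differential-abundance effect on a target population
#'
#' Computes, for every cell, a planted probability of originating from
#' condition C2. The probability is a min-max rescaling of a logit-transformed
#' Gaussian similarity to the target-population centroid in PC space, mapped
#' onto `[0.5, pDA]`: the cell closest to the centroid attains the full DA
#' ratio `pDA`, the farthest cell attains 0.5 (no effect). `pDA < 0.5` plants
#' a depletion (range `[pDA, 0.5]`), and `pDA = 0.5` gives a null dataset.
#'
#' The logit similarity is a saturating ramp in the variance-weighted
#' Euclidean distance `d` to the target centroid (each PC weighted by the
#' square of its variance share, so the planted field follows the structured
#' components rather than the high-dimensional noise radius):
#' `w = clamp((d0 - d) / tau, -W, W)` with `d0` the 90th percentile of the
#' target population's own centroid distances, `tau = d0 / 20` and `W = 4`.
#' Cells well inside the target population saturate at the full DA ratio,
#' cells beyond ~1.2 `d0` sit exactly at 0.5, and the steep transition at the
#' population boundary emulates planting a coherent DA population. Only the
#' ranks of `w` reach the rescaled probability, so any monotone similarity
#' with the same saturation structure is equivalent.
#'
#' @param x a dataset with a `"PCA"` reduced dimension (see [pcaEmbed()]).
#' @param targetPopulation population name present in `x$population`.
#' @param pDA the DA ratio in (0, 1): the maximal enrichment of condition C2
#'   within the target population.
#' @param seed unused (the planting map is deterministic); accepted so grid
#'   drivers can pass one uniformly.
#' @return A \linkS4class{GroundTruth} (labels not yet derived).
#' @export
plantDA <- function(x, targetPopulation, pDA, seed = NULL) {
    if (pDA <= 0 || pDA >= 1) stop("pDA must lie in (0, 1)")
    pop <- x$population
    if (!targetPopulation %in% pop)
        stop("unknown target population: ", targetPopulation)
    emb <- .getEmbedding(x)
    centroid <- colMeans(emb[pop == targetPopulation, , drop = FALSE])
    vw <- apply(emb, 2, stats::var)
    vw <- (vw / max(vw))^2
    d <- sqrt(sweep(emb, 2, centroid)^2 %*% vw)[, 1]
    d0 <- stats::quantile(d[pop == targetPopulation], 0.9, names = FALSE)
    if (d0 == 0) stop("degenerate geometry: all cells at the centroid")
    w <- clamp((d0 - d) / (d0 / 20), -4, 4)
    if (max(w) == min(w))
        stop("degenerate similarity: centroid distances are all equal")
    prob <- (w - min(w)) / (max(w) - min(w)) * (pDA - 0.5) + 0.5
    new("GroundTruth", cellId = colnames(x), w = w, probC2 = prob,
        pDA = pDA, t = NA_real_, label = character(0),
        targetPopulation = targetPopulation)
}

#' Derive three-way ground-truth DA labels
#'
#' Sets the label threshold `t` from the share of the dataset held by the
#' target population and labels each cell `NegLFC` (`P(C2) < t`), `PosLFC`
#' (`P(C2) > 1 - t`) or `NotDA` (otherwise). For an enrichment planting
#' (`pDA > 0.5`), `t = 1 - q` with `q` the `(1 - targetProportion)`-quantile
#' of the planted probabilities, so the `PosLFC` tail holds approximately the
#' target population's share of cells; a depletion planting mirrors this on
#' the lower tail. `t` is clipped to `(0.05, 0.45)`.
#'
#' @param truth a \linkS4class{GroundTruth} from [plantDA()].
#' @param targetProportion the target population's share of cells, in (0, 1).
#' @return The \linkS4class{GroundTruth} with `t` and per-cell labels filled.
#' @export
groundTruthLabels <- function(truth, targetProportion) {
    if (targetProportion <= 0 || targetProportion >= 1)
        stop("targetProportion must lie in (0, 1)")
    p <- truth@probC2
    t <- if (truth@pDA >= 0.5)
        1 - stats::quantile(p, 1 - targetProportion, names = FALSE)
    else
        stats::quantile(p, targetProportion, names = FALSE)
    # when the planted field saturates, the quantile can coincide with the
    # extreme value; back off so the saturated cells themselves stay labelled
    if (truth@pDA > 0.5) t <- max(t, 1 - max(p) + 1e-9)
    if (truth@pDA < 0.5) t <- max(t, min(p) + 1e-9)
    t <- clamp(t, 0.05, 0.45)
    lab <- ifelse(p < t, "NegLFC", ifelse(p > 1 - t, "PosLFC", "NotDA"))
    truth@t <- t
    truth@label <- lab
    validObject(truth)
    truth
}

#' Assign conditions, replicates and samples by the planted probabilities
#'
#' Each cell's condition is drawn `Bernoulli(P(C2))` (C2 on success, C1
#' otherwise) and its replicate uniformly from `R1..Rn`; the sample id is the
#' condition x replicate combination, so a two-condition, three-replicate
#' design yields exactly six samples. If any sample ends up empty the
#' assignment is redrawn (with a warning), up to `retries` times.
#'
#' @param x the dataset.
#' @param truth a \linkS4class{GroundTruth} carrying `P(C2)` per cell.
#' @param nReplicates replicates per condition (default 3).
#' @param seed integer seed for the assignment stream.
#' @param retries redraw bound for empty samples.
#' @return `x` with `colData` columns `condition`, `replicate`, `sample`.
#' @export
assignConditions <- function(x, truth, nReplicates = 3, seed = 1,
                             retries = 20) {
    stopifnot(length(truth@probC2) == ncol(x))
    set.seed(childSeed(seed, "conditions"))
    n <- ncol(x)
    reps <- paste0("R", seq_len(nReplicates))
    for (try in seq_len(retries)) {
        cond <- ifelse(stats::rbinom(n, 1, truth@probC2) == 1, "C2", "C1")
        repl <- sample(reps, n, replace = TRUE)
        samp <- paste(cond, repl, sep = "_")
        expect <- as.vector(outer(c("C1", "C2"), reps, paste, sep = "_"))
        if (all(expect %in% samp)) {
            x$condition <- cond
            x$replicate <- repl
            x$sample <- samp
            S4Vectors::metadata(x)$n_samples <- length(expect)
            return(x)
        }
        warning("empty sample in draw ", try, "; resampling")
    }
    stop("could not produce a design without empty samples after ",
         retries, " draws")
}

#' Inject Gaussian batch effects in PC space
#'
#' One Gaussian shift vector per batch, with i.i.d. entries of standard
#' deviation `batchSd`, is added to the PC profile of every cell in that
#' batch. The unshifted embedding is preserved as `"PCA_original"`.
#' `batchSd = 0` leaves the embedding unchanged.
#'
#' With `by = "sample"` (the default) whole samples are randomly partitioned
#' into batches, re-drawing until every batch contains both conditions. This
#' is the processing-batch structure that makes batch effects a confounder:
#' testing units distorted toward one batch see unequal sample composition,
#' graph methods pair replicates across separated batch clouds, and a batch
#' covariate (defined at the sample level) can absorb the nuisance variation.
#' With `by = "cell"` cells are assigned to batches uniformly at random,
#' independent of sample; the resulting batches are balanced within every
#' sample, so the shift perturbs geometry but confounds nothing.
#'
#' @param x dataset with a `"PCA"` reduced dimension; `by = "sample"`
#'   additionally requires assigned samples ([assignConditions()]).
#' @param batchSd standard deviation of the shift entries (>= 0).
#' @param nBatches number of batches (default 2).
#' @param seed integer seed for assignment and shift draws.
#' @param by assign whole samples (default) or individual cells to batches.
#' @return `x` with `colData$batch` and a shifted `"PCA"` embedding.
#' @export
addBatchEffects <- function(x, batchSd, nBatches = 2, seed = 1,
                            by = c("sample", "cell")) {
    by <- match.arg(by)
    if (batchSd < 0) stop("batchSd must be non-negative")
    emb <- .getEmbedding(x)
    set.seed(childSeed(seed, "batch"))
    batches <- paste0("B", seq_len(nBatches))
    if (by == "cell") {
        batch <- sample(batches, ncol(x), replace = TRUE)
    } else {
        .checkMultiSample(x)
        samples <- sort(unique(x$sample))
        cond <- substr(samples, 1, 2)
        for (try in seq_len(100)) {
            grp <- sample(rep(batches, length.out = length(samples)))
            ok <- all(vapply(batches, function(b)
                length(unique(cond[grp == b])) == 2, logical(1)))
            if (ok) break
        }
        if (!ok) stop("could not place both conditions in every batch")
        batch <- grp[match(x$sample, samples)]
    }
    shift <- matrix(stats::rnorm(nBatches * ncol(emb), 0, batchSd),
                    nBatches, ncol(emb), dimnames = list(batches, NULL))
    SingleCellExperiment::reducedDim(x, "PCA_original") <- emb
    SingleCellExperiment::reducedDim(x, "PCA") <- emb + shift[batch, ,
                                                              drop = FALSE]
    x$batch <- batch
    S4Vectors::metadata(x)$batch_sd <- batchSd
    x
}

#' Subsample one population without replacement
#'
#' Used to build the balanced-cluster variant: other populations are left
#' untouched.
#'
#' @param x dataset.
#' @param population population to thin.
#' @param targetSize cells to keep (<= current size; 0 removes it).
#' @param seed integer seed.
#' @return The subsetted dataset.
#' @export
subsamplePopulation <- function(x, population, targetSize, seed = 1) {
    idx <- which(x$population == population)
    if (!length(idx)) stop("unknown population: ", population)
    if (targetSize > length(idx))
        stop("targetSize exceeds the population size")
    set.seed(childSeed(seed, "subsample"))
    drop <- sample(idx, length(idx) - targetSize)
    if (length(drop)) x[, -drop] else x
}

#' Simulate a series of datasets of increasing size
#'
#' One dataset per requested cell count, sharing all generative parameters;
#' each dataset draws from its own child stream so any element is
#' reproducible independently of the others. Intended for the timing harness.
#'
#' @param sizes vector of cell counts.
#' @param kind,nGenes,dispersion,seed as in [simulateTopology()].
#' @return A list of datasets, one per size.
#' @export
simulateScalingSeries <- function(sizes, kind = "linear", nGenes = 500,
                                  dispersion = 0.5, seed = 1) {
    lapply(sizes, function(n)
        simulateTopology(kind, nCells = n, nGenes = nGenes,
                         dispersion = dispersion,
                         seed = childSeed(seed, paste0("size.", n))))
}
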