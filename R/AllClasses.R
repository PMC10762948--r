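#' @import methods
#' @importFrom Matrix Matrix sparseMatrix colSums rowSums t diag crossprod
#'   Diagonal
#' @importFrom Rcpp sourceCpp
#' @useDynLib scDAbench, .registration = TRUE
NULL

#' Ground-truth differential-abundance annotation
#'
#' Per-cell planted probability of originating from condition C2, together
#' with the underlying logit-transformed centroid similarity, the DA ratio
#' used for planting, the label threshold and the resulting three-way labels.
#'
#' @slot cellId character, one id per cell.
#' @slot w numeric, logit-transformed Gaussian similarity to the target
#'   population centroid in PC space.
#' @slot probC2 numeric, planted probability of condition C2 per cell.
#' @slot pDA numeric(1), the DA ratio (maximal C2 enrichment).
#' @slot t numeric(1), label threshold in (0, 0.5); `NA` until labels are
#'   derived.
#' @slot label character, per-cell label in `NegLFC`, `PosLFC`, `NotDA`
#'   (length 0 until labels are derived).
#' @slot targetPopulation character(1), the planted population.
#'
#' @seealso [plantDA()], [groundTruthLabels()]
#' @export
setClass("GroundTruth",
    representation(cellId = "character", w = "numeric", probC2 = "numeric",
        pDA = "numeric", t = "numeric", label = "character",
        targetPopulation = "character"))

setValidity("GroundTruth", function(object) {
    msg <- NULL
    n <- length(object@cellId)
    if (length(object@w) != n || length(object@probC2) != n)
        msg <- c(msg, "cellId, w and probC2 must have equal length")
    if (length(object@pDA) != 1 || object@pDA <= 0 || object@pDA >= 1)
        msg <- c(msg, "pDA must be a single probability in (0, 1)")
    if (any(!is.finite(object@probC2)))
        msg <- c(msg, "probC2 must be finite")
    if (length(object@label) && length(object@label) != n)
        msg <- c(msg, "label must be empty or one per cell")
    if (length(object@label) &&
        !all(object@label %in% c("NegLFC", "PosLFC", "NotDA")))
        msg <- c(msg, "labels must be NegLFC, PosLFC or NotDA")
    if (length(object@t) == 1 && !is.na(object@t) &&
        (object@t <= 0 || object@t >= 0.5))
        msg <- c(msg, "t must lie in (0, 0.5)")
    if (is.null(msg)) TRUE else msg
})

#' Weighted k-nearest-neighbour cell graph
#'
#' Symmetric non-negative weighted adjacency over cells, plus the cached
#' directed neighbour structure (indices and distances) it was built from.
#' The graph is the shared substrate for the Meld, Cna, Milo, Louvain and
#' DA-seq style methods.
#'
#' @slot adjacency symmetric sparse `dgCMatrix` with zero diagonal.
#' @slot k integer(1), neighbours requested per cell.
#' @slot kernel `"binary"`, `"gaussian"` or `"alpha_decay"`.
#' @slot knnIndex integer matrix cells x k of 1-based neighbour indices,
#'   nearest first.
#' @slot knnDist numeric matrix cells x k of the matching distances.
#'
#' @seealso [buildKnnGraph()]
#' @export
setClass("CellGraph",
    representation(adjacency = "Matrix", k = "integer", kernel = "character",
        knnIndex = "matrix", knnDist = "matrix"))

setValidity("CellGraph", function(object) {
    A <- object@adjacency
    msg <- NULL
    if (nrow(A) != ncol(A)) msg <- c(msg, "adjacency must be square")
    if (any(Matrix::diag(A) != 0)) msg <- c(msg, "diagonal must be zero")
    if (any(A@x < 0)) msg <- c(msg, "weights must be non-negative")
    if (!Matrix::isSymmetric(A, tol = 1e-10))
        msg <- c(msg, "adjacency must be symmetric")
    if (!object@kernel %in% c("binary", "gaussian", "alpha_decay"))
        msg <- c(msg, "unknown kernel")
    if (is.null(msg)) TRUE else msg
})

#' Result of one differential-abundance testing run
#'
#' Per-cell DA-ness scores and directions on a common scale-free contract
#' (higher score = stronger evidence of DA; direction +1 = enriched in C2,
#' -1 = enriched in C1), plus the method's native unit-level test table
#' (hyperspheres, neighbourhoods or clusters).
#'
#' @slot method character(1).
#' @slot cellScore numeric per cell, finite where assessed.
#' @slot cellDirection numeric per cell in \{-1, 0, 1\}.
#' @slot significant logical per cell, the method's own call at its nominal
#'   level.
#' @slot notAssessed logical per cell.
#' @slot unitTable data.frame of unit-level statistics (may have 0 rows).
#' @slot hyperparams named list recording the hyperparameters and seed used.
#'
#' @export
setClass("DAResult",
    representation(method = "character", cellScore = "numeric",
        cellDirection = "numeric", significant = "logical",
        notAssessed = "logical", unitTable = "data.frame",
        hyperparams = "list"))

setValidity("DAResult", function(object) {
    n <- length(object@cellScore)
    msg <- NULL
    if (length(object@cellDirection) != n || length(object@notAssessed) != n ||
        length(object@significant) != n)
        msg <- c(msg, "per-cell slots must have equal length")
    if (any(!is.finite(object@cellScore[!object@notAssessed])))
        msg <- c(msg, "scores must be finite where assessed")
    if (!all(object@cellDirection %in% c(-1, 0, 1)))
        msg <- c(msg, "direction must be -1, 0 or +1")
    if ("p_value" %in% names(object@unitTable)) {
        p <- object@unitTable$p_value
        if (any(p < 0 | p > 1, na.rm = TRUE))
            msg <- c(msg, "unit p-values must lie in [0, 1]")
    }
    if (is.null(msg)) TRUE else msg
})

#' Neighbourhood abundance model (random-walk NAM)
#'
#' The column-stochastic random-walk matrix with self-loops, the per-sample
#' arrival-mass matrix after `steps` steps, and its row-normalized form, the
#' neighbourhood abundance matrix (NAM).
#'
#' @slot markov column-stochastic sparse matrix over cells.
#' @slot steps integer(1) random-walk length.
#' @slot arrivals samples x cells arrival-mass matrix.
#' @slot nam samples x cells row-stochastic NAM.
#' @slot samples character sample ids (row order of `nam`).
#'
#' @seealso [buildNAM()], [cnaTest()]
#' @export
setClass("NamModel",
    representation(markov = "Matrix", steps = "integer", arrivals = "matrix",
        nam = "matrix", samples = "character"))

setValidity("NamModel", function(object) {
    msg <- NULL
    if (max(abs(Matrix::colSums(object@markov) - 1)) > 1e-8)
        msg <- c(msg, "markov columns must sum to 1")
    if (nrow(object@nam) &&
        max(abs(rowSums(object@nam) - 1)) > 1e-8)
        msg <- c(msg, "nam rows must sum to 1")
    if (length(object@samples) != nrow(object@nam))
        msg <- c(msg, "one sample id per nam row")
    if (is.null(msg)) TRUE else msg
})
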