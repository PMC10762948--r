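#' Derive a named child seed from a master seed
#'
#' Experiments vary one factor at a time, so each randomized stage (topology,
#' planting, condition assignment, batch, method) draws from its own stream.
#' The child seed is a deterministic 31-bit hash of the master seed and the
#' stream name.
#'
#' @param seed integer master seed.
#' @param stream character stream name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
childSeed <- function(seed, stream) {
    h <- as.numeric(seed) %% 2147483647
    for (ch in utf8ToInt(stream))
        h <- (h * 31 + ch) %% 2147483647
    as.integer(h)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
.assertCondition <- function(condition) {
    if (length(unique(condition)) < 2)
        stop("both conditions C1 and C2 must be present")
}

# condition factor as 0/1 with C2 = 1
.cond01 <- function(condition) as.integer(condition == "C2")

# colData columns required by the DA methods
.checkMultiSample <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    need <- c("sample", "condition", "replicate")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        stop("dataset lacks colData column(s): ", paste(miss, collapse = ", "),
             "; call assignConditions() first")
    invisible(TRUE)
}

# embedding matrix from an SCE (default "PCA")
.getEmbedding <- function(x, name = "PCA") {
    if (is.matrix(x)) return(x)
    rd <- SingleCellExperiment::reducedDims(x)
    if (!name %in% names(rd))
        stop("reduced dimension '", name, "' not found; run pcaEmbed() first")
    rd[[name]]
}
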