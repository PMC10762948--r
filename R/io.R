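#' Write a dataset as Matrix Market counts plus TSV metadata
#'
#' Files written under `dir`: `counts.mtx` (genes x cells), `genes.tsv`,
#' `cells.tsv` (columns `cell_id`, `population`, and where present `sample`,
#' `condition`, `replicate`, `batch`), and `pca.tsv` if a PCA embedding
#' exists.
#'
#' @param x the dataset.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(x, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    m <- SummarizedExperiment::assay(x, "counts")
    Matrix::writeMM(as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                    file.path(dir, "counts.mtx"))
    utils::write.table(data.frame(gene = rownames(m)),
                       file.path(dir, "genes.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    keep <- intersect(c("cell_id", "population", "sample", "condition",
                        "replicate", "batch"), colnames(cd))
    utils::write.table(cd[, keep, drop = FALSE],
                       file.path(dir, "cells.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    rd <- SingleCellExperiment::reducedDims(x)
    if ("PCA" %in% names(rd))
        utils::write.table(as.data.frame(rd[["PCA"]]),
                           file.path(dir, "pca.tsv"), sep = "\t",
                           row.names = FALSE, quote = FALSE)
    invisible(dir)
}

#' Read a dataset written by [writeDataset()]
#'
#' @param dir directory holding `counts.mtx`, `genes.tsv`, `cells.tsv` and
#'   optionally `pca.tsv`.
#' @return A [SingleCellExperiment::SingleCellExperiment].
#' @export
readDataset <- function(dir) {
    m <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
    genes <- utils::read.delim(file.path(dir, "genes.tsv"))
    cells <- utils::read.delim(file.path(dir, "cells.tsv"))
    rownames(m) <- genes$gene
    colnames(m) <- cells$cell_id
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = m),
        colData = S4Vectors::DataFrame(cells))
    pcaFile <- file.path(dir, "pca.tsv")
    if (file.exists(pcaFile))
        SingleCellExperiment::reducedDim(sce, "PCA") <-
            as.matrix(utils::read.delim(pcaFile))
    sce
}

#' Write ground truth as TSV
#'
#' Columns: `cell_id`, `prob_c2`, `w`, `label` (where derived), plus the
#' scalars `p_da`, `t` and the target population repeated per row for a
#' self-contained file.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeGroundTruth <- function(truth, file) {
    df <- data.frame(cell_id = truth@cellId, prob_c2 = truth@probC2,
                     w = truth@w,
                     label = if (length(truth@label)) truth@label
                             else NA_character_,
                     p_da = truth@pDA, t = truth@t,
                     target_population = truth@targetPopulation)
    utils::write.table(df, file, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    invisible(file)
}

#' Read ground truth written by [writeGroundTruth()]
#' @param file TSV path.
#' @return A \linkS4class{GroundTruth}.
#' @export
readGroundTruth <- function(file) {
    df <- utils::read.delim(file)
    new("GroundTruth", cellId = as.character(df$cell_id), w = df$w,
        probC2 = df$prob_c2, pDA = df$p_da[1], t = df$t[1],
        label = if (all(is.na(df$label))) character(0)
                else as.character(df$label),
        targetPopulation = as.character(df$target_population[1]))
}

#' Export a cell graph as an edge-list TSV
#'
#' One row per undirected edge (upper triangle): `source`, `target`
#' (1-based cell indices) and `weight`.
#'
#' @param graph a \linkS4class{CellGraph}.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeCellGraph <- function(graph, file) {
    A <- Matrix::triu(graph@adjacency)
    tri <- Matrix::summary(A)
    utils::write.table(data.frame(source = tri$i, target = tri$j,
                                  weight = tri$x),
                       file, sep = "\t", row.names = FALSE, quote = FALSE)
    invisible(file)
}

#' Write a DA testing result
#'
#' Writes `<prefix>_cells.tsv` (cell_id, method, score, direction,
#' significant, not_assessed), `<prefix>_units.tsv` (the method's unit
#' table), and `<prefix>_manifest.json` (method and hyperparameters).
#'
#' @param result a \linkS4class{DAResult}.
#' @param prefix output path prefix.
#' @param cellIds optional cell ids (default integer index).
#' @return The manifest path, invisibly.
#' @export
writeDAResult <- function(result, prefix, cellIds = NULL) {
    n <- length(result@cellScore)
    if (is.null(cellIds)) cellIds <- as.character(seq_len(n))
    cells <- data.frame(cell_id = cellIds, method = result@method,
                        score = result@cellScore,
                        direction = result@cellDirection,
                        significant = result@significant,
                        not_assessed = result@notAssessed)
    utils::write.table(cells, paste0(prefix, "_cells.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(result@unitTable, paste0(prefix, "_units.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    manifest <- paste0(prefix, "_manifest.json")
    jsonlite::write_json(list(method = result@method,
                              hyperparams = result@hyperparams),
                         manifest, auto_unbox = TRUE, digits = NA,
                         null = "null")
    invisible(manifest)
}
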