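#' Collapse three-way ground-truth labels to binary
#'
#' Both `PosLFC` and `NegLFC` are treated as the positive class (the cell is
#' differentially abundant in either direction); `NotDA` is negative.
#'
#' @param labels character labels, or a \linkS4class{GroundTruth} with
#'   derived labels.
#' @return Logical vector, `TRUE` for DA cells.
#' @export
binarizeTruth <- function(labels) {
    if (is(labels, "GroundTruth")) labels <- daLabels(labels)
    if (!all(labels %in% c("NegLFC", "PosLFC", "NotDA")))
        stop("labels must be NegLFC, PosLFC or NotDA")
    labels != "NotDA"
}

#' Percentile threshold grid over a score distribution
#'
#' Thresholds at the stated percentiles of the method's own DA-score
#' distribution (default 0% to 100% in 1% increments, 101 values).
#'
#' @param scores numeric DA scores.
#' @param percentiles percent points in `[0, 100]`.
#' @return Numeric thresholds, one per percentile.
#' @export
thresholdGrid <- function(scores, percentiles = seq(0, 100, by = 1)) {
    if (!length(scores)) stop("scores must be non-empty")
    stats::quantile(scores, percentiles / 100, names = FALSE, type = 7)
}

#' Confusion counts at one threshold
#'
#' A cell is predicted DA iff its score is at or above the threshold. Cells
#' that a method did not assess should carry score 0 (they count as
#' predicted-negative at any positive threshold).
#'
#' @param scores numeric DA scores.
#' @param truth logical binarized ground truth ([binarizeTruth()]).
#' @param threshold numeric cutoff.
#' @param direction optional per-cell predicted direction (+1 enriched in
#'   C2, -1 in C1); with `labels`, switches on strict direction matching.
#' @param labels optional three-way ground-truth labels; a predicted
#'   positive on a DA cell counts as a true positive only if its direction
#'   matches the label's direction (PosLFC = +1, NegLFC = -1), otherwise as
#'   a false positive (and the DA cell counts as missed).
#' @return Named integer vector `tp`, `fp`, `tn`, `fn`.
#' @export
confusionAt <- function(scores, truth, threshold, direction = NULL,
                        labels = NULL) {
    if (!length(scores)) stop("empty input")
    if (length(scores) != length(truth)) stop("lengths differ")
    pred <- scores >= threshold
    if (is.null(direction) || is.null(labels)) {
        return(c(tp = sum(pred & truth), fp = sum(pred & !truth),
                 tn = sum(!pred & !truth), fn = sum(!pred & truth)))
    }
    want <- ifelse(labels == "PosLFC", 1, ifelse(labels == "NegLFC", -1, 0))
    hit <- pred & truth & direction == want
    c(tp = sum(hit), fp = sum(pred & !hit),
      tn = sum(!pred & !truth), fn = sum(truth & !hit))
}

#' False and true positive rates from confusion counts
#'
#' @param counts named vector from [confusionAt()].
#' @return `c(fpr, tpr)` with `fpr = FP / (FP + TN)`,
#'   `tpr = TP / (TP + FN)`.
#' @export
fprTpr <- function(counts) {
    if (counts["fp"] + counts["tn"] == 0 || counts["tp"] + counts["fn"] == 0)
        stop("a class is missing; rates are undefined")
    c(fpr = unname(counts["fp"] / (counts["fp"] + counts["tn"])),
      tpr = unname(counts["tp"] / (counts["tp"] + counts["fn"])))
}

.sweepGrid <- function(scores, truth, percentiles) {
    thr <- thresholdGrid(scores, percentiles)
    t(vapply(thr, function(t) confusionAt(scores, truth, t), numeric(4)))
}

#' Area under the ROC curve via the percentile-threshold protocol
#'
#' Sweeps thresholds at percentiles of the score distribution, computes the
#' (FPR, TPR) pair at each, anchors the curve at (0,0) and (1,1), orders the
#' points by FPR (then TPR) and integrates by the trapezoid rule.
#'
#' @inheritParams confusionAt
#' @param percentiles percent points for [thresholdGrid()].
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, truth, percentiles = seq(0, 100, by = 1)) {
    if (length(unique(truth)) < 2)
        stop("both classes must be present in the truth")
    cm <- .sweepGrid(scores, truth, percentiles)
    fpr <- cm[, "fp"] / (cm[, "fp"] + cm[, "tn"])
    tpr <- cm[, "tp"] / (cm[, "tp"] + cm[, "fn"])
    fpr <- c(0, fpr, 1); tpr <- c(0, tpr, 1)
    o <- order(fpr, tpr)
    fpr <- fpr[o]; tpr <- tpr[o]
    sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Area under the precision-recall curve via the threshold protocol
#'
#' Precision and recall are computed at each percentile threshold; thresholds
#' with no predicted positives are dropped; the precision at recall 0 is
#' carried over from the highest-threshold point, and the area is the
#' trapezoid over recall-ordered points.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`.
#' @export
auprc <- function(scores, truth, percentiles = seq(0, 100, by = 1)) {
    if (!any(truth)) stop("no positive cells in the truth")
    cm <- .sweepGrid(scores, truth, percentiles)
    keep <- (cm[, "tp"] + cm[, "fp"]) > 0
    cm <- cm[keep, , drop = FALSE]
    rec <- cm[, "tp"] / (cm[, "tp"] + cm[, "fn"])
    prec <- cm[, "tp"] / (cm[, "tp"] + cm[, "fp"])
    o <- order(rec, -prec)
    rec <- rec[o]; prec <- prec[o]
    rec <- c(0, rec); prec <- c(prec[1], prec)
    sum(diff(rec) * (utils::head(prec, -1) + utils::tail(prec, -1)) / 2)
}

#' Aggregate benchmark metric records
#'
#' Per (method, dataset, DA ratio): the median AUROC/AUPRC over target
#' populations and seeds. Per (method, dataset): the mean of the per-ratio
#' medians — the benchmark's headline "average" scores.
#'
#' @param records data.frame with columns `method`, `dataset`, `da_ratio`,
#'   `target_population`, `seed`, `auroc`, `auprc`.
#' @return A list with data.frames `medians` (per ratio) and `summary`
#'   (per method and dataset).
#' @export
aggregateMetrics <- function(records) {
    need <- c("method", "dataset", "da_ratio", "auroc", "auprc")
    if (!all(need %in% colnames(records)))
        stop("records lack required columns")
    if (!nrow(records)) {
        warning("no records to aggregate")
        return(list(medians = records, summary = records))
    }
    med <- stats::aggregate(cbind(auroc, auprc) ~ method + dataset + da_ratio,
                            data = records, FUN = stats::median)
    summ <- stats::aggregate(cbind(auroc, auprc) ~ method + dataset,
                             data = med, FUN = mean)
    list(medians = med[order(med$method, med$dataset, med$da_ratio), ],
         summary = summ[order(summ$method, summ$dataset), ])
}
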