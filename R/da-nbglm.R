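#' Per-unit negative-binomial GLM test of condition
#'
#' Fits, for each testing unit (hypersphere, neighbourhood or cluster), a
#' negative-binomial GLM of the per-sample cell counts on condition (and an
#' optional batch covariate) with a log link and `log(totals)` offset, and
#' tests the condition coefficient by a likelihood-ratio test. Dispersion is
#' estimated per unit by maximum likelihood; when the ML estimate diverges or
#' fails (e.g. underdispersed counts) the fit falls back to a Poisson model
#' (one summary warning reports how many units fell back).
#'
#' @param unitCounts units x samples matrix of non-negative integer counts.
#' @param condition per-sample condition, values `"C1"`/`"C2"` (or any
#'   two-level factor; the second level is the enriched direction).
#' @param batch optional per-sample batch factor, added as a covariate.
#' @param totals per-sample offset totals. The default (`NULL`) uses
#'   median-of-ratios size factors computed from `unitCounts`, which assumes
#'   most units are not differentially abundant and centres their log fold
#'   changes at zero; raw per-sample cell totals can be passed instead, but
#'   note that planting an enrichment then makes every background unit appear
#'   (genuinely) depleted in relative abundance.
#' @return A data.frame with one row per unit: `logFC` (log2 fold change of
#'   C2 vs C1), `p_value`, and `not_assessed` (all-zero or unfittable units,
#'   reported with `logFC = 0`, `p = 1`).
#' @examples
#' counts <- rbind(a = c(1, 1, 1, 8, 8, 8), b = c(5, 4, 6, 5, 5, 5))
#' nbGlmTest(counts, rep(c("C1", "C2"), each = 3),
#'           totals = rep(100, 6))
#' @export
nbGlmTest <- function(unitCounts, condition, batch = NULL, totals = NULL) {
    unitCounts <- as.matrix(unitCounts)
    S <- ncol(unitCounts)
    if (length(condition) != S)
        stop("condition must have one entry per sample")
    cond <- factor(condition)
    if (nlevels(cond) != 2) stop("condition must have exactly two levels")
    if (min(table(cond)) < 2)
        stop("at least 2 samples per condition are required")
    if (any(unitCounts < 0)) stop("counts must be non-negative")
    if (is.null(totals)) totals <- .sizeFactors(unitCounts)
    off <- log(pmax(totals, .Machine$double.eps))

    X0 <- matrix(1, S, 1)
    if (!is.null(batch)) {
        b <- factor(batch)
        if (nlevels(b) > 1)
            X0 <- cbind(X0, stats::model.matrix(~b)[, -1, drop = FALSE])
    }
    X1 <- cbind(X0, cond = as.integer(cond) - 1L)
    condCol <- ncol(X1)

    nUnits <- nrow(unitCounts)
    logFC <- numeric(nUnits)
    pval <- rep(1, nUnits)
    na <- logical(nUnits)
    nFallback <- 0L

    for (u in seq_len(nUnits)) {
        y <- unitCounts[u, ]
        if (all(y == 0)) { na[u] <- TRUE; next }
        res <- tryCatch({
            f1 <- suppressWarnings(
                stats::glm.fit(X1, y, offset = off, family = stats::poisson()))
            # theta.ml warns both when the estimate diverges upward
            # (iteration limit) and downward (truncated at zero); with six
            # samples the likelihood in theta is often flat and the failure
            # direction is numerically arbitrary, so any warning or error
            # deterministically selects the Poisson fallback
            theta <- tryCatch(
                MASS::theta.ml(y, pmax(f1$fitted.values, 1e-8), limit = 50),
                error = function(e) Inf, warning = function(w) Inf)
            if (!is.finite(theta) || theta > 1e6) {
                nFallback <- nFallback + 1L
                fam <- stats::poisson()
            } else fam <- MASS::negative.binomial(theta)
            full <- suppressWarnings(
                stats::glm.fit(X1, y, offset = off, family = fam))
            null <- suppressWarnings(
                stats::glm.fit(X0, y, offset = off, family = fam))
            stat <- max(null$deviance - full$deviance, 0)
            list(lfc = full$coefficients[condCol] / log(2),
                 p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
        }, error = function(e) NULL)
        if (is.null(res) || !is.finite(res$lfc) || !is.finite(res$p)) {
            na[u] <- TRUE
        } else {
            logFC[u] <- res$lfc
            pval[u] <- min(max(res$p, 0), 1)
        }
    }
    if (nFallback > 0)
        warning(nFallback, " unit(s) used a Poisson fallback ",
                "(dispersion estimate diverged)")
    data.frame(logFC = logFC, p_value = pval, not_assessed = na)
}

#' Median-of-ratios per-sample size factors
#'
#' @param unitCounts units x samples count matrix.
#' @return Positive per-sample factors (geometric mean 1); falls back to
#'   relative column sums when no unit has all-positive counts.
#' @noRd
.sizeFactors <- function(unitCounts) {
    pos <- rowSums(unitCounts > 0) == ncol(unitCounts)
    if (sum(pos) >= 2) {
        lc <- log(unitCounts[pos, , drop = FALSE])
        ratios <- lc - rowMeans(lc)
        sf <- exp(apply(ratios, 2, stats::median))
    } else {
        cs <- colSums(unitCounts)
        sf <- cs / exp(mean(log(pmax(cs, 1))))
    }
    pmax(sf, .Machine$double.eps)
}

#' Spatial FDR: density-weighted Benjamini-Hochberg control
#'
#' Implements the weighted step-up rule: with p-values sorted ascending and
#' per-unit density weights `w`, the rejection threshold is the largest
#' `p_(i)` satisfying `p_(i) <= alpha * sum(w_(1..i)) / sum(w)`; all units at
#' or below it are significant. With equal weights this is exactly the
#' Benjamini-Hochberg procedure. Weighting each unit by the reciprocal of its
#' local density controls false discoveries across volume rather than across
#' units. Weighted-BH adjusted values (the monotone `p * sum(w) / cumsum(w)`
#' envelope) are returned for score construction.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param weights positive per-unit density weights (reciprocal density).
#' @param alpha target spatial FDR level.
#' @return A list: `significant` (logical), `maxP` (the rejection threshold,
#'   `NA` if none), `adjusted` (weighted-BH adjusted values).
#' @export
spatialFDR <- function(p, weights = rep(1, length(p)), alpha = 0.1) {
    if (length(p) != length(weights)) stop("lengths of p and weights differ")
    if (!length(p))
        return(list(significant = logical(0), maxP = NA_real_,
                    adjusted = numeric(0)))
    if (any(weights <= 0)) stop("weights must be positive")
    ord <- order(p)
    cw <- cumsum(weights[ord])
    tot <- cw[length(cw)]
    ok <- p[ord] <= alpha * cw / tot
    maxP <- if (any(ok)) max(p[ord][ok]) else NA_real_
    sig <- if (is.na(maxP)) rep(FALSE, length(p)) else p <= maxP
    adjSorted <- rev(cummin(rev(pmin(p[ord] * tot / cw, 1))))
    adjusted <- numeric(length(p))
    adjusted[ord] <- adjSorted
    list(significant = sig, maxP = maxP, adjusted = adjusted)
}
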