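# Shared plumbing for the unit-counting DA methods.

# Counting columns: per sample, or per sample x batch pseudo-sample when the
# batch covariate is modelled (batch is assigned per cell, so a per-sample
# batch factor does not exist; splitting sample columns by batch puts a
# batch term into the GLM design instead).
.countingDesign <- function(x, useBatch = FALSE) {
    .checkMultiSample(x)
    if (useBatch && is.null(x$batch))
        stop("batch covariate requested but the dataset has no batch labels")
    if (useBatch) {
        unit <- paste(x$sample, x$batch, sep = ".")
        lev <- sort(unique(unit))
        meta <- do.call(rbind, strsplit(lev, ".", fixed = TRUE))
        cond <- substr(meta[, 1], 1, 2)
        batch <- meta[, 2]
    } else {
        unit <- x$sample
        lev <- sort(unique(unit))
        cond <- substr(lev, 1, 2)
        batch <- NULL
    }
    colIdx <- match(unit, lev)
    list(colIdx = colIdx, levels = lev, condition = cond, batch = batch,
         totals = tabulate(colIdx, length(lev)))
}

# units x columns count matrix for a list of member index vectors
.unitCounts <- function(members, colIdx, nCols) {
    t(vapply(members, function(m) tabulate(colIdx[m], nCols),
             integer(nCols)))
}

# max-score aggregation: per cell, the best (1 - adjusted) over containing
# units, with that unit's direction and significance
.bestUnitPerCell <- function(members, adjusted, logFC, significant, nCells) {
    score <- rep(0, nCells)
    dir <- rep(0, nCells)
    sig <- rep(FALSE, nCells)
    seen <- rep(FALSE, nCells)
    for (u in seq_along(members)) {
        m <- members[[u]]
        seen[m] <- TRUE
        s <- 1 - adjusted[u]
        better <- m[score[m] < s]
        score[better] <- s
        dir[better] <- sign(logFC[u])
        if (significant[u]) sig[m] <- TRUE
    }
    list(score = score, direction = dir, significant = sig,
         notAssessed = !seen)
}
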