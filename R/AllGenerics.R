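#' @rdname DAResult-class
#' @param object,x a \linkS4class{DAResult}, \linkS4class{GroundTruth},
#'   \linkS4class{CellGraph} or \linkS4class{NamModel}.
#' @export
setGeneric("cellScore", function(x) standardGeneric("cellScore"))

#' @rdname DAResult-class
#' @export
setGeneric("cellDirection", function(x) standardGeneric("cellDirection"))

#' @rdname DAResult-class
#' @export
setGeneric("unitTable", function(x) standardGeneric("unitTable"))

#' @rdname DAResult-class
#' @export
setGeneric("notAssessed", function(x) standardGeneric("notAssessed"))

#' @rdname DAResult-class
#' @export
setGeneric("isSignificant", function(x) standardGeneric("isSignificant"))

#' @rdname GroundTruth-class
#' @export
setGeneric("probC2", function(x) standardGeneric("probC2"))

#' @rdname GroundTruth-class
#' @export
setGeneric("daLabels", function(x) standardGeneric("daLabels"))

#' @rdname CellGraph-class
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname NamModel-class
#' @export
setGeneric("nam", function(x) standardGeneric("nam"))

#' @rdname DAResult-class
#' @export
setMethod("cellScore", "DAResult", function(x) x@cellScore)

#' @rdname DAResult-class
#' @export
setMethod("cellDirection", "DAResult", function(x) x@cellDirection)

#' @rdname DAResult-class
#' @export
setMethod("unitTable", "DAResult", function(x) x@unitTable)

#' @rdname DAResult-class
#' @export
setMethod("notAssessed", "DAResult", function(x) x@notAssessed)

#' @rdname DAResult-class
#' @export
setMethod("isSignificant", "DAResult", function(x) x@significant)

#' @rdname GroundTruth-class
#' @export
setMethod("probC2", "GroundTruth", function(x) x@probC2)

#' @rdname GroundTruth-class
#' @export
setMethod("daLabels", "GroundTruth", function(x) {
    if (!length(x@label))
        stop("labels not derived yet; call groundTruthLabels() first")
    x@label
})

#' @rdname CellGraph-class
#' @export
setMethod("adjacency", "CellGraph", function(x) x@adjacency)

#' @rdname NamModel-class
#' @export
setMethod("nam", "NamModel", function(x) x@nam)

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth: ", length(object@cellId),
        " cells, target population '", object@targetPopulation,
        "', DA ratio ", object@pDA, "\n", sep = "")
    if (length(object@label)) {
        cat("  t =", signif(object@t, 4), "; labels:\n")
        print(table(object@label))
    } else cat("  labels not derived yet\n")
})

setMethod("show", "CellGraph", function(object) {
    cat("CellGraph:", nrow(object@adjacency), "cells, k =", object@k,
        ", kernel =", object@kernel, ",",
        length(object@adjacency@x) / 2, "undirected edges\n")
})

setMethod("show", "DAResult", function(object) {
    cat("DAResult [", object@method, "]: ", length(object@cellScore),
        " cells (", sum(object@notAssessed), " not assessed), ",
        nrow(object@unitTable), " testing units, ",
        sum(object@significant), " cells significant\n", sep = "")
})

setMethod("show", "NamModel", function(object) {
    cat("NamModel:", nrow(object@nam), "samples x", ncol(object@nam),
        "cells,", object@steps, "random-walk steps\n")
})
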