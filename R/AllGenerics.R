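#' @include AllClasses.R
NULL

#' Cell-type labels of an object
#' @param x a CCCExpression, OverexpressionCalls or CCCNetwork
#' @return character vector of cell-type labels
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' Ligand node labels
#' @param x a CCCNetwork or LRInteractionTable
#' @return character vector of ligand gene symbols
#' @export
setGeneric("ligandNodes", function(x) standardGeneric("ligandNodes"))

#' Production matrix A (cell x ligand, binary)
#' @param x a CCCNetwork
#' @return binary matrix
#' @export
setGeneric("productionMatrix", function(x) standardGeneric("productionMatrix"))

#' Binding matrix B (ligand x cell, receptor-species counts)
#' @param x a CCCNetwork
#' @return non-negative integer matrix
#' @export
setGeneric("bindingMatrix", function(x) standardGeneric("bindingMatrix"))

#' Interaction pairs as a data.frame
#' @param x an LRInteractionTable
#' @return data.frame with ligand/receptor/confidence/heteromericGroup
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))

#' @describeIn cellTypes cell-type labels of the samples
#' @export
setMethod("cellTypes", "CCCExpression",
          function(x) as.character(x$cellType))

#' @describeIn cellTypes cell types with over-expression calls
#' @export
setMethod("cellTypes", "OverexpressionCalls",
          function(x) names(x@ligands))

#' @describeIn cellTypes cell nodes of the network (incl. "Others" if present)
#' @export
setMethod("cellTypes", "CCCNetwork", function(x) x@cellNodes)

#' @describeIn ligandNodes ligand nodes of the network
#' @export
setMethod("ligandNodes", "CCCNetwork", function(x) x@ligandNodes)

#' @describeIn ligandNodes distinct ligands in the interaction table
#' @export
setMethod("ligandNodes", "LRInteractionTable",
          function(x) unique(x@pairs$ligand))

#' @describeIn productionMatrix the A matrix
#' @export
setMethod("productionMatrix", "CCCNetwork", function(x) x@production)

#' @describeIn bindingMatrix the B matrix
#' @export
setMethod("bindingMatrix", "CCCNetwork", function(x) x@binding)

#' @describeIn interactions the pair table
#' @export
setMethod("interactions", "LRInteractionTable",
          function(x) as.data.frame(x@pairs))

setMethod("show", "CCCExpression", function(object) {
    cat("CCCExpression:", nrow(object), "genes x", ncol(object), "samples\n")
    tab <- table(as.character(object$cellType))
    cat(" ", length(tab), "cell types (",
        paste0(names(tab), ":", as.integer(tab), collapse = " "), ")\n")
    rd <- SummarizedExperiment::rowData(object)
    if ("role" %in% colnames(rd)) {
        rt <- table(rd$role)
        cat("  roles:", paste0(names(rt), "=", as.integer(rt),
                               collapse = " "), "\n")
    }
})

setMethod("show", "LRInteractionTable", function(object) {
    p <- object@pairs
    cat("LRInteractionTable:", nrow(p), "pairs,",
        length(unique(p$ligand)), "ligands,",
        length(unique(p$receptor)), "receptors\n")
    ng <- length(unique(p$heteromericGroup[!is.na(p$heteromericGroup)]))
    if (ng) cat(" ", ng, "heteromeric receptor complex group(s)\n")
})

setMethod("show", "OverexpressionCalls", function(object) {
    cat("OverexpressionCalls (FDR", object@fdr, ", minWins",
        object@minWins, ")\n")
    for (ct in names(object@ligands))
        cat(sprintf("  %-8s %3d ligands %3d receptors\n", ct,
                    length(object@ligands[[ct]]),
                    length(object@receptors[[ct]])))
})

setMethod("show", "CCCNetwork", function(object) {
    A <- object@production; B <- object@binding
    edges <- sum(vapply(seq_along(object@ligandNodes), function(j)
        sum(A[, j] == 1) * sum(B[j, ] >= 1), numeric(1)))
    cat("CCCNetwork:", length(object@cellNodes), "cell nodes,",
        length(object@ligandNodes), "ligand nodes\n")
    cat("  production edges:", sum(A), " binding edges:", sum(B >= 1),
        " cell-to-cell relationships:", edges, "\n")
    if (object@heteromericMode)
        cat("  heteromeric receptor complexes collapsed\n")
})

setMethod("show", "CompartmentModel", function(object) {
    cat("CompartmentModel:", length(object@compartments), "compartments,",
        object@nSims, "simulations, seed", object@seed, "\n")
    for (cp in object@compartments)
        cat(sprintf("  %-6s P = %-4g %d ligand(s)\n", cp,
                    object@reachProb[[cp]],
                    length(object@ligandSets[[cp]])))
})

#' Over-expression call accessors
#'
#' @param x an OverexpressionCalls object
#' @param cellType optional single cell type; if omitted the full named list
#'   is returned
#' @return character vector (or named list) of called gene symbols
#' @export
calledLigands <- function(x, cellType = NULL) {
    stopifnot(is(x, "OverexpressionCalls"))
    if (is.null(cellType)) x@ligands else x@ligands[[cellType]]
}

#' @rdname calledLigands
#' @export
calledReceptors <- function(x, cellType = NULL) {
    stopifnot(is(x, "OverexpressionCalls"))
    if (is.null(cellType)) x@receptors else x@receptors[[cellType]]
}
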