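#' Build the directional bipartite cell-cell communication network
#'
#' Edges follow the production/binding rule: if cell B over-expresses
#' ligand x and cell A over-expresses a receptor for x, a communication
#' arrow runs B -> A. The production matrix A is binary (cell x ligand);
#' the binding matrix B (ligand x cell) counts receptor species per the
#' modeling assumption that more receptor species means a higher chance the
#' ligand binds the cell. In heteromeric mode, receptors sharing a complex
#' group count once, and only when every subunit is over-expressed.
#'
#' Ligands bound by a modeled cell but produced by none gain a production
#' edge from the aggregate \code{"Others"} node (the stem-cell-factor
#' situation: the receptor is on a blood cell, the ligand comes from
#' non-hematopoietic niche cells); ligands produced but bound by no modeled
#' cell are absorbed by \code{"Others"} (binding weight 1). Ligands with
#' neither producer nor binder are dropped.
#'
#' @param calls an \linkS4class{OverexpressionCalls}
#' @param lr an \linkS4class{LRInteractionTable}
#' @param heteromericMode collapse receptor complexes (default FALSE:
#'   subunits counted independently)
#' @param includeOthers add the aggregate "Others" node (default TRUE)
#' @return a \linkS4class{CCCNetwork}
#' @export
buildNetwork <- function(calls, lr, heteromericMode = FALSE,
                         includeOthers = TRUE) {
    stopifnot(is(calls, "OverexpressionCalls"),
              is(lr, "LRInteractionTable"))
    p <- as.data.frame(lr@pairs)
    ligU <- unique(p$ligand)
    recU <- unique(p$receptor)
    types <- names(calls@ligands)
    unknown <- setdiff(unlist(c(calls@ligands, calls@receptors)),
                       union(ligU, recU))
    if (length(unknown))
        warning(length(unknown), " called gene(s) not in the interaction ",
                "table were ignored")
    ligands <- ligU
    A <- matrix(0, length(types), length(ligands),
                dimnames = list(types, ligands))
    for (ctype in types)
        A[ctype, intersect(calls@ligands[[ctype]], ligands)] <- 1
    B <- matrix(0L, length(ligands), length(types),
                dimnames = list(ligands, types))
    for (ctype in types) {
        rec <- intersect(calls@receptors[[ctype]], recU)
        for (lg in ligands) {
            sub <- p[p$ligand == lg, , drop = FALSE]
            if (heteromericMode) {
                cnt <- 0L
                grp <- sub$heteromericGroup
                # complexes: one count per group, all subunits required
                for (g in unique(grp[!is.na(grp)])) {
                    subunits <- sub$receptor[!is.na(grp) & grp == g]
                    if (all(subunits %in% rec)) cnt <- cnt + 1L
                }
                cnt <- cnt + sum(sub$receptor[is.na(grp)] %in% rec)
            } else {
                cnt <- sum(sub$receptor %in% rec)
            }
            B[lg, ctype] <- cnt
        }
    }
    produced <- colSums(A) > 0
    bound <- rowSums(B) > 0
    if (includeOthers) {
        keep <- produced | bound
        A <- A[, keep, drop = FALSE]
        B <- B[keep, , drop = FALSE]
        othersProd <- as.numeric(!produced[keep] & bound[keep])
        othersBind <- as.integer(produced[keep] & !bound[keep])
        A <- rbind(A, Others = othersProd)
        B <- cbind(B, Others = othersBind)
        cells <- c(types, "Others")
    } else {
        keep <- produced & bound
        A <- A[, keep, drop = FALSE]
        B <- B[keep, , drop = FALSE]
        cells <- types
    }
    new("CCCNetwork", cellNodes = cells,
        ligandNodes = colnames(A) %||% character(0),
        production = A, binding = B,
        heteromericMode = heteromericMode)
}

#' Ligand production network (projection)
#'
#' @param net a \linkS4class{CCCNetwork}
#' @param producingOnly drop cells that produce no ligand (default FALSE)
#' @return the binary cell x ligand matrix A
#' @export
productionNetwork <- function(net, producingOnly = FALSE) {
    stopifnot(is(net, "CCCNetwork"))
    A <- net@production
    if (producingOnly) A <- A[rowSums(A) > 0, , drop = FALSE]
    A
}

#' Ligand binding network (projection)
#'
#' @param net a \linkS4class{CCCNetwork}
#' @param bindingOnly drop cells that bind no ligand (default FALSE)
#' @return the ligand x cell receptor-species-count matrix B
#' @export
bindingNetwork <- function(net, bindingOnly = FALSE) {
    stopifnot(is(net, "CCCNetwork"))
    B <- net@binding
    if (bindingOnly) B <- B[, colSums(B) > 0, drop = FALSE]
    B
}

#' Rank cell nodes by produced and bound ligand counts
#'
#' Bound ligands are counted as presence (at least one receptor species),
#' collapsing the species multiplicity of the binding matrix.
#'
#' @param net a \linkS4class{CCCNetwork}
#' @param sortBy order rows by \code{"produced"}, \code{"bound"} or leave
#'   in node order (\code{"none"}, default)
#' @return data.frame (cell, n_produced_ligands, n_bound_ligands)
#' @export
rankCellsByDegree <- function(net, sortBy = c("none", "produced", "bound")) {
    stopifnot(is(net, "CCCNetwork"))
    sortBy <- match.arg(sortBy)
    if (!length(net@cellNodes))
        return(data.frame(cell = character(0),
                          n_produced_ligands = integer(0),
                          n_bound_ligands = integer(0)))
    out <- data.frame(cell = net@cellNodes,
                      n_produced_ligands = as.integer(rowSums(
                          net@production)),
                      n_bound_ligands = as.integer(colSums(
                          net@binding >= 1)))
    if (sortBy == "produced")
        out <- out[order(-out$n_produced_ligands), , drop = FALSE]
    if (sortBy == "bound")
        out <- out[order(-out$n_bound_ligands), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Export a CCCNetwork
#'
#' \code{asIgraph} returns the bipartite directed multigraph with a node
#' \code{kind} attribute (\code{"cell"}/\code{"ligand"}) and binding edges
#' weighted by receptor-species count; \code{writeNetworkGraphML} writes
#' GraphML; \code{writeNetworkEdgeList} writes a long-format TSV
#' (\code{from}, \code{to}, \code{edge_type}, \code{weight}).
#'
#' @param net a \linkS4class{CCCNetwork}
#' @return an \link[igraph]{igraph} object
#' @export
asIgraph <- function(net) {
    stopifnot(is(net, "CCCNetwork"))
    A <- net@production; B <- net@binding
    edges <- character(0); etype <- character(0); w <- numeric(0)
    for (j in net@ligandNodes) {
        prods <- net@cellNodes[A[, j] == 1]
        if (length(prods)) {
            edges <- c(edges, rbind(prods, j))
            etype <- c(etype, rep("production", length(prods)))
            w <- c(w, rep(1, length(prods)))
        }
        binders <- net@cellNodes[B[j, ] >= 1]
        if (length(binders)) {
            edges <- c(edges, rbind(j, binders))
            etype <- c(etype, rep("binding", length(binders)))
            w <- c(w, B[j, binders])
        }
    }
    g <- igraph::make_empty_graph(directed = TRUE) +
        igraph::vertices(net@cellNodes, kind = "cell") +
        igraph::vertices(net@ligandNodes, kind = "ligand")
    if (length(edges))
        g <- g + igraph::edges(edges, edge_type = etype, weight = w)
    g
}

#' @rdname asIgraph
#' @param path destination path
#' @export
writeNetworkGraphML <- function(net, path) {
    igraph::write_graph(asIgraph(net), path, format = "graphml")
    invisible(path)
}

#' @rdname asIgraph
#' @export
writeNetworkEdgeList <- function(net, path) {
    g <- asIgraph(net)
    el <- igraph::as_edgelist(g)
    df <- data.frame(from = el[, 1], to = el[, 2],
                     edge_type = igraph::E(g)$edge_type,
                     weight = igraph::E(g)$weight)
    writeTSV(df, path)
}

#' @rdname asIgraph
#' @export
writeNetworkMatrices <- function(net, path) {
    writeTSV(as.data.frame(net@production), paste0(path, "_production.tsv"),
             rowNames = TRUE)
    writeTSV(as.data.frame(net@binding), paste0(path, "_binding.tsv"),
             rowNames = TRUE)
    invisible(path)
}
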