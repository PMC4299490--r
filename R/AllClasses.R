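#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' CCCExpression: expression data with per-sample cell-type labels
#'
#' Extends \linkS4class{SummarizedExperiment}. Rows are genes (unique
#' symbols, upper case by convention), columns are samples. The
#' \code{colData} must carry a \code{cellType} factor/character column and
#' every cell type must have at least two samples (the rank-sum test used
#' downstream needs ranks within each group). An optional \code{role} column
#' in \code{rowData} marks genes as \code{"ligand"}, \code{"receptor"} or
#' \code{"housekeeping"}.
#'
#' @slot .Data inherited SummarizedExperiment structure
#' @export
setClass("CCCExpression", contains = "SummarizedExperiment")

setValidity("CCCExpression", function(object) {
    msg <- NULL
    if (!"cellType" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'cellType' column")
    else {
        ct <- as.character(object$cellType)
        if (anyNA(ct)) msg <- c(msg, "cellType labels must not be NA")
        tab <- table(ct)
        if (any(tab < 2))
            msg <- c(msg, paste0("every cell type needs >= 2 samples; ",
                                 "offending: ",
                                 paste(names(tab)[tab < 2], collapse = ", ")))
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "duplicate gene symbols (pre-average probes per gene)")
    if (length(SummarizedExperiment::assays(object)) >= 1) {
        v <- SummarizedExperiment::assay(object, 1)
        if (any(v < 0, na.rm = TRUE))
            msg <- c(msg, "expression values must be non-negative")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a CCCExpression object
#'
#' @param values numeric gene-by-sample matrix of non-negative expression
#'   values (rownames = gene symbols, colnames = sample ids)
#' @param cellType character vector of cell-type labels, one per sample
#' @param role optional character vector per gene
#'   (\code{"ligand"}/\code{"receptor"}/\code{"housekeeping"})
#' @return a \linkS4class{CCCExpression}
#' @export
CCCExpression <- function(values, cellType, role = NULL) {
    values <- as.matrix(values)
    if (is.null(rownames(values)))
        stop("values must have gene symbols as rownames")
    if (is.null(colnames(values)))
        colnames(values) <- paste0("S", seq_len(ncol(values)))
    cd <- DataFrame(cellType = as.character(cellType),
                    row.names = colnames(values))
    rd <- if (is.null(role)) DataFrame(row.names = rownames(values))
          else DataFrame(role = role, row.names = rownames(values))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = values), colData = cd, rowData = rd)
    new("CCCExpression", se)
}

#' LRInteractionTable: curated ligand-receptor interaction pairs
#'
#' One row per (ligand, receptor) pair, with an optional confidence score in
#' [0, 1] (default 1) and an optional heteromeric complex group label tying
#' receptor subunits that are required jointly (class-1 cytokine receptors
#' such as the IL6R/IL6ST complex).
#'
#' @slot pairs a \link[S4Vectors]{DataFrame} with columns \code{ligand},
#'   \code{receptor}, \code{confidence}, \code{heteromericGroup}
#' @export
setClass("LRInteractionTable", representation(pairs = "DataFrame"))

setValidity("LRInteractionTable", function(object) {
    p <- object@pairs
    msg <- NULL
    need <- c("ligand", "receptor", "confidence", "heteromericGroup")
    if (!all(need %in% colnames(p)))
        return(paste("pairs must have columns", paste(need, collapse = ", ")))
    if (anyDuplicated(paste(p$ligand, p$receptor)))
        msg <- c(msg, "(ligand, receptor) pairs must be unique")
    conf <- p$confidence
    if (any(!is.na(conf) & (conf < 0 | conf > 1)))
        msg <- c(msg, "confidence must lie in [0, 1]")
    grp <- p$heteromericGroup
    grp <- grp[!is.na(grp)]
    if (length(grp)) {
        sz <- table(grp)
        if (any(sz < 2))
            msg <- c(msg, paste0("heteromeric groups need >= 2 receptor ",
                                 "subunits: ",
                                 paste(names(sz)[sz < 2], collapse = ", ")))
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct an LRInteractionTable
#'
#' Gene symbols are case-normalized to upper case; duplicated pairs are
#' collapsed (keeping the maximum confidence) with a warning.
#'
#' @param ligand,receptor character vectors of gene symbols (recycled
#'   together)
#' @param confidence optional numeric in [0, 1]; default 1
#' @param heteromericGroup optional character label; receptors sharing a
#'   label form one complex that only binds when all subunits are present
#' @return an \linkS4class{LRInteractionTable}
#' @export
LRInteractionTable <- function(ligand, receptor, confidence = NULL,
                               heteromericGroup = NULL) {
    ligand <- toupper(as.character(ligand))
    receptor <- toupper(as.character(receptor))
    n <- length(ligand)
    stopifnot(length(receptor) == n)
    if (is.null(confidence)) confidence <- rep(1, n)
    confidence <- as.numeric(confidence)
    confidence[is.na(confidence)] <- 1
    if (is.null(heteromericGroup))
        heteromericGroup <- rep(NA_character_, n)
    heteromericGroup <- as.character(heteromericGroup)
    key <- paste(ligand, receptor)
    if (anyDuplicated(key)) {
        warning("collapsing ", sum(duplicated(key)),
                " duplicated ligand-receptor pair(s)")
        ord <- order(key, -confidence)
        keep <- ord[!duplicated(key[ord])]
        keep <- sort(keep)
        ligand <- ligand[keep]; receptor <- receptor[keep]
        confidence <- confidence[keep]
        heteromericGroup <- heteromericGroup[keep]
    }
    new("LRInteractionTable",
        pairs = DataFrame(ligand = ligand, receptor = receptor,
                          confidence = confidence,
                          heteromericGroup = heteromericGroup))
}

#' OverexpressionCalls: per-cell-type over-expressed ligands and receptors
#'
#' @slot ligands named list of character vectors, one per cell type
#' @slot receptors named list of character vectors, one per cell type
#' @slot fdr the Benjamini-Hochberg threshold used
#' @slot minWins minimum number of pairwise comparisons a gene must win
#' @export
setClass("OverexpressionCalls",
         representation(ligands = "list", receptors = "list",
                        fdr = "numeric", minWins = "integer"))

setValidity("OverexpressionCalls", function(object) {
    msg <- NULL
    if (!identical(names(object@ligands), names(object@receptors)))
        msg <- c(msg, "ligands and receptors must cover the same cell types")
    if (object@fdr <= 0 || object@fdr >= 1)
        msg <- c(msg, "fdr must lie in (0, 1)")
    if (object@minWins < 1L)
        msg <- c(msg, "minWins must be >= 1")
    if (is.null(msg)) TRUE else msg
})

#' CCCNetwork: directional bipartite cell-cell communication network
#'
#' Cell nodes (modeled cell types plus, optionally, an aggregate
#' \code{"Others"} population) and ligand nodes are linked by two matrices:
#' the binary production matrix \code{A} (cell x ligand; \code{A[i, j] = 1}
#' iff cell i over-expresses ligand j) and the binding matrix \code{B}
#' (ligand x cell; \code{B[j, i]} counts receptor species -- or complexes,
#' in heteromeric mode -- that cell i over-expresses for ligand j). A
#' directed cell-to-cell edge i -> k via ligand j exists iff
#' \code{A[i, j] == 1} and \code{B[j, k] >= 1}.
#'
#' @slot cellNodes ordered cell labels
#' @slot ligandNodes ordered ligand gene symbols
#' @slot production binary cell x ligand matrix
#' @slot binding non-negative integer ligand x cell matrix
#' @slot heteromericMode logical; TRUE if complexes were collapsed
#' @export
setClass("CCCNetwork",
         representation(cellNodes = "character", ligandNodes = "character",
                        production = "matrix", binding = "matrix",
                        heteromericMode = "logical"))

setValidity("CCCNetwork", function(object) {
    msg <- NULL
    A <- object@production; B <- object@binding
    if (!identical(dim(A), c(length(object@cellNodes),
                             length(object@ligandNodes))))
        msg <- c(msg, "production must be cell x ligand")
    if (!identical(dim(B), c(length(object@ligandNodes),
                             length(object@cellNodes))))
        msg <- c(msg, "binding must be ligand x cell")
    if (length(A) && !all(A %in% c(0, 1)))
        msg <- c(msg, "production must be binary")
    if (length(B) && (any(B < 0) || any(B != round(B))))
        msg <- c(msg, "binding must hold non-negative integer counts")
    if (length(object@ligandNodes)) {
        iso <- rowSums(B) == 0 & colSums(A) == 0
        if (any(iso))
            msg <- c(msg, paste0("isolated ligand node(s): ",
                                 paste(object@ligandNodes[iso],
                                       collapse = ", ")))
    }
    if (is.null(msg)) TRUE else msg
})

#' CompartmentModel: OR-gate model of ligand reach to the stem cell
#'
#' Four developmental compartments by default -- HSCe (the stem-cell-enriched
#' population itself), PC (progenitors), MCN (mature cells in the niche) and
#' MCP (mature cells in the periphery) -- each holding the set of ligands its
#' cells over-express and a probability that a ligand produced there reaches
#' the stem cell. A Monte-Carlo simulation draws per-ligand Bernoulli
#' indicators per compartment and takes the OR (union) across compartments.
#'
#' @slot compartments ordered compartment labels
#' @slot ligandSets named list (compartment -> character vector of ligands)
#' @slot reachProb named numeric in [0, 1], one per compartment
#' @slot nSims number of Monte-Carlo simulations
#' @slot seed RNG seed
#' @export
setClass("CompartmentModel",
         representation(compartments = "character", ligandSets = "list",
                        reachProb = "numeric", nSims = "integer",
                        seed = "integer"))

setValidity("CompartmentModel", function(object) {
    msg <- NULL
    cps <- object@compartments
    if (!identical(sort(names(object@ligandSets)), sort(cps)))
        msg <- c(msg, "ligandSets must be named by the compartments")
    if (!identical(sort(names(object@reachProb)), sort(cps)))
        msg <- c(msg, "reachProb must be named by the compartments")
    if (any(object@reachProb < 0 | object@reachProb > 1))
        msg <- c(msg, "reach probabilities must lie in [0, 1]")
    if (object@nSims < 1L) msg <- c(msg, "nSims must be >= 1")
    if (is.null(msg)) TRUE else msg
})

#' Construct a CompartmentModel
#'
#' Defaults follow the hematopoietic localization assumptions: autocrine
#' ligands always reach the stem cell (P = 1), progenitor-compartment
#' ligands reach with P = 0.8, niche-resident mature cells with P = 0.7 and
#' peripheral mature cells, separated by the niche-blood barrier, with
#' P = 0.1.
#'
#' @param ligandSets named list compartment -> ligand character vector
#' @param reachProb named numeric of reach probabilities
#' @param nSims number of simulations (default 500)
#' @param seed RNG seed
#' @return a \linkS4class{CompartmentModel}
#' @export
CompartmentModel <- function(ligandSets,
                             reachProb = c(HSCe = 1, PC = 0.8,
                                           MCN = 0.7, MCP = 0.1),
                             nSims = 500L, seed = 1L) {
    cps <- names(ligandSets)
    if (is.null(cps)) stop("ligandSets must be a named list")
    reachProb <- reachProb[cps]
    if (anyNA(reachProb))
        stop("reachProb must provide a probability for every compartment")
    new("CompartmentModel", compartments = cps,
        ligandSets = lapply(ligandSets, function(x) toupper(as.character(x))),
        reachProb = reachProb, nSims = as.integer(nSims),
        seed = as.integer(seed))
}
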