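# Pairwise adjusted p-values: for each cell type c, a gene x (other cell
# type) matrix of BH-adjusted one-sided rank-sum p-values (c greater).
# Adjustment is per pairwise comparison, across the gene universe.
.pairwiseAdjP <- function(data, geneUniverse) {
    v <- SummarizedExperiment::assay(data, 1)[geneUniverse, , drop = FALSE]
    ct <- as.character(data$cellType)
    types <- unique(ct)
    idx <- split(seq_along(ct), ct)
    if (any(lengths(idx) < 2L))
        stop("every cell type needs >= 2 samples for the rank-sum test")
    out <- list()
    for (a in types) {
        others <- setdiff(types, a)
        m <- matrix(NA_real_, length(geneUniverse), length(others),
                    dimnames = list(geneUniverse, others))
        for (b in others) {
            p <- rowWilcoxGreater(v, idx[[a]], idx[[b]])
            m[, b] <- stats::p.adjust(p, method = "BH")
        }
        out[[a]] <- m
    }
    out
}

.callsFromAdjP <- function(adjp, fdr, minWins) {
    lapply(adjp, function(m) {
        wins <- rowSums(m <= fdr)
        rownames(m)[wins >= minWins]
    })
}

#' Call differentially over-expressed ligand and receptor genes
#'
#' For each cell type and each gene of the universe, a one-sided (greater)
#' Wilcoxon rank-sum test is run against every other cell type; p-values
#' are Benjamini-Hochberg adjusted per pairwise comparison across the
#' universe, and a gene is called over-expressed in a cell type when its
#' adjusted p-value is at or below \code{fdr} in at least \code{minWins}
#' comparisons (default 6 of the 11 possible among 12 cell types).
#'
#' @param data a \linkS4class{CCCExpression}
#' @param lr an \linkS4class{LRInteractionTable} defining the
#'   ligand/receptor universes; genes absent from \code{data} are ignored
#'   with a warning
#' @param fdr adjusted-p threshold in (0, 1); default 0.1
#' @param minWins minimum number of pairwise comparisons won
#' @param geneUniverse optional explicit universe for the BH adjustment;
#'   default: all ligand and receptor genes of \code{lr} present in
#'   \code{data}
#' @return an \linkS4class{OverexpressionCalls}
#' @export
callOverexpressed <- function(data, lr, fdr = 0.1, minWins = 6L,
                              geneUniverse = NULL) {
    stopifnot(is(data, "CCCExpression"), is(lr, "LRInteractionTable"))
    if (fdr <= 0 || fdr >= 1) stop("fdr must lie in (0, 1)")
    nTypes <- length(unique(as.character(data$cellType)))
    minWins <- as.integer(minWins)
    if (minWins < 1L || minWins > nTypes - 1L)
        stop("minWins must lie in [1, number of cell types - 1]")
    ligU <- unique(lr@pairs$ligand)
    recU <- unique(lr@pairs$receptor)
    if (is.null(geneUniverse)) geneUniverse <- union(ligU, recU)
    missing <- setdiff(geneUniverse, rownames(data))
    if (length(missing))
        warning(length(missing), " universe gene(s) absent from the ",
                "dataset were ignored")
    geneUniverse <- intersect(geneUniverse, rownames(data))
    if (!length(geneUniverse)) stop("empty gene universe")
    adjp <- .pairwiseAdjP(data, geneUniverse)
    called <- .callsFromAdjP(adjp, fdr, minWins)
    new("OverexpressionCalls",
        ligands = lapply(called, intersect, x = ligU),
        receptors = lapply(called, intersect, x = recU),
        fdr = fdr, minWins = minWins)
}

#' Select the FDR threshold by ROC against benchmark receptors
#'
#' Candidate thresholds are scored against a benchmark of known cell
#' type-associated receptors: sensitivity is the fraction of benchmark
#' (cell type, receptor) pairs recovered by the calls, specificity the
#' fraction of non-benchmark (cell type, receptor-universe gene) pairs not
#' called. The chosen threshold maximizes Youden's J (sensitivity +
#' specificity - 1); ties go to the smaller (more conservative) threshold.
#' Since it is not obvious whether negatives should range over the receptor
#' universe or all genes, the table reports specificity under both.
#'
#' @param data a \linkS4class{CCCExpression}
#' @param lr an \linkS4class{LRInteractionTable}
#' @param benchmark named list: cell type -> character vector of known
#'   receptors; receptors absent from the receptor universe are dropped
#'   with a warning
#' @param candidateFdrs thresholds to test (default the classic ladder
#'   1\%, 5\%, 10\%, 20\%, 25\%)
#' @param minWins as in \code{\link{callOverexpressed}}
#' @return list with \code{chosen} (the selected threshold) and
#'   \code{table} (per-threshold sensitivity, specificity on the receptor
#'   universe, specificity on all universe genes, Youden's J)
#' @export
selectFdrByROC <- function(data, lr, benchmark,
                           candidateFdrs = c(0.01, 0.05, 0.10, 0.20, 0.25),
                           minWins = 6L) {
    stopifnot(is(data, "CCCExpression"), is(lr, "LRInteractionTable"))
    if (!length(candidateFdrs)) stop("candidateFdrs must be non-empty")
    if (!length(benchmark) || !sum(lengths(benchmark)))
        stop("benchmark must name at least one receptor")
    recU <- intersect(unique(lr@pairs$receptor), rownames(data))
    allU <- intersect(union(unique(lr@pairs$ligand), recU), rownames(data))
    benchmark <- lapply(benchmark, function(r) {
        r <- toupper(r)
        drop <- setdiff(r, recU)
        if (length(drop))
            warning("benchmark receptor(s) outside the receptor universe ",
                    "dropped: ", paste(drop, collapse = ", "))
        intersect(r, recU)
    })
    benchmark <- benchmark[lengths(benchmark) > 0]
    if (!length(benchmark))
        stop("no benchmark receptor lies in the receptor universe")
    adjp <- .pairwiseAdjP(data, allU)
    types <- names(adjp)
    nBench <- sum(lengths(benchmark))
    res <- lapply(candidateFdrs, function(f) {
        called <- .callsFromAdjP(adjp, f, as.integer(minWins))
        tp <- sum(vapply(names(benchmark), function(ctype) {
            if (!ctype %in% types) return(0L)
            length(intersect(benchmark[[ctype]],
                             intersect(called[[ctype]], recU)))
        }, integer(1)))
        negCalls <- function(universe) {
            neg <- 0L; negCalled <- 0L
            for (ctype in types) {
                bset <- if (ctype %in% names(benchmark))
                    benchmark[[ctype]] else character(0)
                neg <- neg + length(setdiff(universe, bset))
                negCalled <- negCalled +
                    length(setdiff(intersect(called[[ctype]], universe),
                                   bset))
            }
            1 - negCalled / neg
        }
        specRec <- negCalls(recU)
        specAll <- negCalls(allU)
        sens <- tp / nBench
        data.frame(fdr = f, sensitivity = sens,
                   specificity = specRec,
                   specificity_all_genes = specAll,
                   youdenJ = sens + specRec - 1)
    })
    tab <- do.call(rbind, res)
    best <- tab$youdenJ >= max(tab$youdenJ) - 1e-12
    chosen <- min(tab$fdr[best])
    list(chosen = chosen, table = tab)
}

#' Read a benchmark receptor list
#'
#' Two-column TSV with header \code{cell_type} and \code{receptor}.
#'
#' @param path path to the TSV file
#' @return named list: cell type -> receptor symbols
#' @export
readBenchmark <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("cell_type", "receptor") %in% colnames(df)))
        stop("benchmark file needs 'cell_type' and 'receptor' columns")
    lapply(split(toupper(df$receptor), df$cell_type), unique)
}

#' Write over-expression calls as long-format TSV
#'
#' Columns: \code{cell_type}, \code{gene}, \code{role}.
#'
#' @param calls an \linkS4class{OverexpressionCalls}
#' @param path destination path
#' @export
writeCalls <- function(calls, path) {
    stopifnot(is(calls, "OverexpressionCalls"))
    rows <- list()
    for (ctype in names(calls@ligands)) {
        if (length(calls@ligands[[ctype]]))
            rows[[length(rows) + 1L]] <- data.frame(
                cell_type = ctype, gene = calls@ligands[[ctype]],
                role = "ligand")
        if (length(calls@receptors[[ctype]]))
            rows[[length(rows) + 1L]] <- data.frame(
                cell_type = ctype, gene = calls@receptors[[ctype]],
                role = "receptor")
    }
    df <- if (length(rows)) do.call(rbind, rows)
          else data.frame(cell_type = character(0), gene = character(0),
                          role = character(0))
    writeTSV(df, path)
}
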