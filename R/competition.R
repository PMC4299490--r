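#' Read a cell-frequency vector
#'
#' Two-column TSV with header \code{cell_type} and \code{frequency}.
#' Frequencies are normalized to sum to 1 on load.
#'
#' @param path path to the TSV file
#' @return named numeric frequency vector summing to 1
#' @export
readFrequencies <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("cell_type", "frequency") %in% colnames(df)))
        stop("frequency file needs 'cell_type' and 'frequency' columns")
    f <- stats::setNames(as.numeric(df$frequency), df$cell_type)
    if (any(f < 0) || sum(f) <= 0) stop("frequencies must be non-negative ",
                                        "with a positive sum")
    f / sum(f)
}

#' Potential of apparent competition between cell types
#'
#' Two cell types compete "apparently" when they draw on the same ligands;
#' the pressure cell j exerts on cell i grows with j's share of the uptake
#' of the ligands in i's binding portfolio. With weights
#' \code{w[i, k] = f[i] * R[i, k]} (cell frequency times receptor-species
#' count), the competition of j on i is
#' \deqn{P_{ij} = \sum_k \frac{w_{ik}}{\sum_m w_{im}} \cdot
#'       \frac{w_{jk}}{\sum_l w_{lk}}}
#' i.e. i's portfolio share on ligand k times j's share of ligand k's
#' total uptake. Every row sums to 1 by construction; the diagonal is the
#' cell's self-competition share.
#'
#' Cells with zero total weighted binding have an undefined row and are
#' excluded with a warning rather than given a fabricated uniform row.
#'
#' @param B non-negative ligand x cell receptor-count matrix
#' @param f named frequency vector covering the cells of \code{B}
#'   (normalized internally)
#' @return square row-stochastic PAC matrix (cell x cell)
#' @export
computePAC <- function(B, f) {
    B <- as.matrix(B)
    cells <- colnames(B)
    if (is.null(cells)) stop("B must have cell names as colnames")
    if (!all(cells %in% names(f)))
        stop("frequency vector must cover every cell in B; missing: ",
             paste(setdiff(cells, names(f)), collapse = ", "))
    f <- f[cells]
    if (any(f < 0) || sum(f) <= 0)
        stop("frequencies must be non-negative with a positive sum")
    f <- f / sum(f)
    W <- t(B) * f            # cell x ligand: w[i, k] = f_i * R_ik
    tot <- rowSums(W)
    zero <- tot == 0
    if (any(zero)) {
        warning("cell(s) with zero weighted binding excluded: ",
                paste(cells[zero], collapse = ", "))
        W <- W[!zero, , drop = FALSE]
        cells <- cells[!zero]
        tot <- tot[!zero]
    }
    if (nrow(W) == 0) stop("no cell with positive weighted binding")
    ligTot <- colSums(W)
    share <- W / tot                           # portfolio share of i on k
    uptake <- sweep(W, 2, ligTot, "/")         # j's share of ligand k
    uptake[, ligTot == 0] <- 0
    P <- share %*% t(uptake)
    dimnames(P) <- list(cells, cells)
    P
}

#' PAC under named cell-frequency scenarios
#'
#' Computes a PAC matrix per scenario (e.g. the mono-nucleated-cell
#' compartment, where the most abundant cell type is the major ligand
#' sink, versus a progenitor-enriched compartment where the stem-cell
#' fraction regains ligand access) and summarizes, per cell, the dominant
#' competitor (the arg-max of its row excluding none).
#'
#' @param net a \linkS4class{CCCNetwork}
#' @param scenarios named list of named frequency vectors; cells missing
#'   from a scenario (e.g. "Others") are dropped from that scenario's
#'   matrix
#' @return named list per scenario: \code{pac} (matrix) and
#'   \code{dominant} (named character: per-cell arg-max competitor)
#' @export
pacScenarios <- function(net, scenarios) {
    stopifnot(is(net, "CCCNetwork"))
    if (is.null(names(scenarios))) stop("scenarios must be named")
    B <- net@binding
    lapply(scenarios, function(f) {
        f <- f / sum(f)
        keep <- intersect(colnames(B), names(f))
        Bs <- B[, keep, drop = FALSE]
        Bs <- Bs[rowSums(Bs) > 0, , drop = FALSE]
        P <- computePAC(Bs, f)
        dominant <- colnames(P)[apply(P, 1, which.max)]
        list(pac = P,
             dominant = stats::setNames(dominant, rownames(P)))
    })
}

#' Classic unweighted potential of apparent competition
#'
#' The frequency-free special case: equal frequencies, receptor counts as
#' given. Provided as the reference the weighted form reduces to under
#' uniform frequencies (used in cross-checks).
#'
#' @param B non-negative ligand x cell matrix
#' @return row-stochastic PAC matrix
#' @export
classicPAC <- function(B) {
    B <- as.matrix(B)
    f <- stats::setNames(rep(1 / ncol(B), ncol(B)), colnames(B))
    computePAC(B, f)
}

#' Write a PAC matrix as square TSV
#'
#' @param P PAC matrix from \code{\link{computePAC}}
#' @param path destination path
#' @export
writePAC <- function(P, path) writeTSV(as.data.frame(P), path,
                                       rowNames = TRUE)
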