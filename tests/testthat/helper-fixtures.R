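# Shared fixtures built in code.

# Minimal over-expression calls object.
makeCalls <- function(ligands, receptors, fdr = 0.1, minWins = 1L) {
    types <- union(names(ligands), names(receptors))
    lig <- setNames(lapply(types, function(ct)
        toupper(ligands[[ct]] %||% character(0))), types)
    rec <- setNames(lapply(types, function(ct)
        toupper(receptors[[ct]] %||% character(0))), types)
    new("OverexpressionCalls", ligands = lig, receptors = rec,
        fdr = fdr, minWins = as.integer(minWins))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny expression set: 2 cell types x 5 replicates, one gene planted high
# in the first type (5v5 gives exact rank-sum p = 1/252, which survives
# the BH adjustment over the 4-gene universe at FDR 10%).
makeTinyExpression <- function(shift = 5, seed = 42L) {
    set.seed(seed)
    v <- matrix(rnorm(5 * 10, mean = 6, sd = 0.5), 5, 10,
                dimnames = list(c("LIGA", "LIGB", "RECA", "RECB", "HK1"),
                                paste0("s", 1:10)))
    v["LIGA", 1:5] <- v["LIGA", 1:5] + shift
    CCCExpression(pmax(v, 0), cellType = rep(c("T1", "T2"), each = 5),
                  role = c("ligand", "ligand", "receptor", "receptor",
                           "housekeeping"))
}

# Brute-force classic potential of apparent competition (unweighted,
# independent of the package implementation): triple loop over the
# definition.
bruteClassicPAC <- function(R) {
    n <- ncol(R)
    P <- matrix(0, n, n, dimnames = list(colnames(R), colnames(R)))
    for (i in seq_len(n)) for (j in seq_len(n)) {
        s <- 0
        for (k in seq_len(nrow(R))) {
            if (R[k, i] == 0) next
            s <- s + (R[k, i] / sum(R[, i])) * (R[k, j] / sum(R[k, ]))
        }
        P[i, j] <- s
    }
    P
}

# Exhaustively enumerated hypergeometric mean/sd standardization of k.
enumHyperZ <- function(N, m, n, k) {
    ks <- max(0, n + m - N):min(n, m)
    pmf <- vapply(ks, function(x)
        choose(m, x) * choose(N - m, n - x) / choose(N, n), numeric(1))
    mu <- sum(ks * pmf)
    sd <- sqrt(sum((ks - mu)^2 * pmf))
    (k - mu) / sd
}
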