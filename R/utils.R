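# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
    expr
}

#' Row-wise one-sided Wilcoxon rank-sum test
#'
#' For every row of \code{x}, tests whether the values in columns
#' \code{idx1} are stochastically greater than those in columns \code{idx2}
#' (alternative "greater"). Uses the exact rank-sum null when both groups
#' have at most \code{exactMax} observations and the row has no ties,
#' otherwise the tie-corrected normal approximation with continuity
#' correction. Matches \code{stats::wilcox.test} row by row but is
#' vectorized over genes.
#'
#' @param x numeric matrix (genes x samples)
#' @param idx1,idx2 column indices of the two groups
#' @param exactMax largest per-group size for which the exact null is used
#' @return numeric vector of one-sided p-values, one per row
#' @export
rowWilcoxGreater <- function(x, idx1, idx2, exactMax = 10L) {
    n1 <- length(idx1); n2 <- length(idx2)
    stopifnot(n1 >= 1L, n2 >= 1L)
    xc <- x[, c(idx1, idx2), drop = FALSE]
    nr <- nrow(xc)
    rk <- matrix(0, nr, n1 + n2)
    tiecorr <- numeric(nr)
    for (g in seq_len(nr)) {
        r <- rank(xc[g, ])
        rk[g, ] <- r
        tt <- table(xc[g, ])
        tiecorr[g] <- sum(tt^3 - tt)
    }
    u <- rowSums(rk[, seq_len(n1), drop = FALSE]) - n1 * (n1 + 1) / 2
    p <- numeric(nr)
    exact <- tiecorr == 0 & n1 <= exactMax & n2 <= exactMax
    if (any(exact))
        p[exact] <- stats::pwilcox(u[exact] - 1, n1, n2,
                                   lower.tail = FALSE)
    if (any(!exact)) {
        nn <- n1 + n2
        sigma2 <- (n1 * n2 / 12) *
            ((nn + 1) - tiecorr[!exact] / (nn * (nn - 1)))
        z <- (u[!exact] - n1 * n2 / 2 - 0.5) / sqrt(sigma2)
        p[!exact] <- stats::pnorm(z, lower.tail = FALSE)
    }
    pmin(p, 1)
}

# TSV writer with fixed conventions used by all module writers.
writeTSV <- function(df, path, rowNames = FALSE) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = rowNames,
                       col.names = if (rowNames) NA else TRUE)
    invisible(path)
}
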