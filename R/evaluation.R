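# Benchmark utilities scoring the pipeline against the generator's planted
# truth. Used by the package's own validation studies.

# Best-matching label accuracy: relabel `assignment` by the permutation of
# its labels that maximizes agreement with `truth` (exhaustive over
# permutations; co-cluster counts are small).
.permutations <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
        for (rest in .permutations(v[-i]))
            out[[length(out) + 1L]] <- c(v[i], rest)
    out
}

#' Label accuracy under the best label matching
#'
#' @param assignment named integer/character cluster labels
#' @param truth named reference labels (same names)
#' @return best fraction of items on which a relabeling of
#'   \code{assignment} agrees with \code{truth}
#' @export
labelMatchAccuracy <- function(assignment, truth) {
    common <- intersect(names(assignment), names(truth))
    a <- as.character(assignment[common])
    t_ <- as.character(truth[common])
    labsA <- unique(a)
    labsT <- unique(t_)
    if (length(labsA) > 8)
        stop("too many labels for exhaustive matching")
    pad <- max(0, length(labsA) - length(labsT))
    labsT <- c(labsT, paste0(".pad", seq_len(pad)))
    best <- 0
    for (perm in .permutations(labsT[seq_along(labsA)])) {
        mapped <- perm[match(a, labsA)]
        best <- max(best, mean(mapped == t_))
    }
    best
}

#' Planted-structure recovery study
#'
#' Runs the full pipeline on freshly generated synthetic datasets and
#' scores it against the planted truth, per seed: (a) recovery and false
#' discovery proportion of planted over-expression calls under the default
#' promiscuous design; (b) the silhouette-selected module count and
#' whether the partition of the 12 modeled cell types equals the planted
#' partition; (c) co-clustering label accuracy on the block-structured
#' variant of the same design (binding promiscuity 0), where the binding
#' matrix has planted blocks and the only off-block noise is false calls.
#'
#' @param nSeeds number of independent generator seeds
#' @param fdr,minWins over-expression calling parameters
#' @param baseSeed first seed; seed i is \code{baseSeed + i - 1}
#' @return data.frame with one row per seed: \code{seed},
#'   \code{recovery}, \code{fdp}, \code{selectedK},
#'   \code{partitionExact}, \code{coclusterAccuracy}
#' @export
plantedRecoveryStudy <- function(nSeeds = 20L, fdr = 0.1, minWins = 6L,
                                 baseSeed = 100L) {
    rows <- lapply(seq_len(nSeeds), function(i) {
        seed <- as.integer(baseSeed + i - 1L)
        # (a) + (b): default design, promiscuous binding
        d <- syntheticDesign(seed = seed)
        dat <- generateExpression(d)
        lr <- generateLRTable(d)
        calls <- callOverexpressed(dat, lr, fdr = fdr, minWins = minWins)
        planted <- metadata(dat)$planted
        rec <- tot <- fp <- ncall <- 0
        for (ct in colnames(planted)) {
            truth <- rownames(planted)[planted[, ct]]
            got <- c(calledLigands(calls, ct), calledReceptors(calls, ct))
            rec <- rec + length(intersect(truth, got))
            tot <- tot + length(truth)
            fp <- fp + length(setdiff(got, truth))
            ncall <- ncall + length(got)
        }
        net <- buildNetwork(calls, lr)
        A <- productionNetwork(net)[d$cellTypes, , drop = FALSE]
        A <- A[, colSums(A) > 0, drop = FALSE]
        part <- clusterProduction(A)
        truthMod <- rep(names(d$productionModules),
                        lengths(d$productionModules))
        names(truthMod) <- unlist(d$productionModules)
        exact <- part$k == length(d$productionModules) &&
            labelMatchAccuracy(part$assignment, truthMod) == 1
        # (c): block-structured binding variant of the same design
        db <- syntheticDesign(seed = seed, bindingPromiscuity = 0,
                              nOrphanBound = 0L, nOrphanProduced = 0L)
        datb <- generateExpression(db)
        lrb <- generateLRTable(db)
        callsb <- callOverexpressed(datb, lrb, fdr = fdr,
                                    minWins = minWins)
        netb <- buildNetwork(callsb, lrb)
        B <- bindingNetwork(netb)[, db$cellTypes, drop = FALSE]
        B <- B[rowSums(B) > 0, , drop = FALSE]
        cc <- coclusterBinding(B, k = length(db$productionModules),
                               seed = 0L)
        archb <- metadata(datb)$architecture
        truthB <- c(archb$ligModule[rownames(B)], truthMod)
        acc <- labelMatchAccuracy(c(cc$rowAssignment, cc$colAssignment),
                                  truthB)
        data.frame(seed = seed, recovery = rec / tot, fdp = fp / ncall,
                   selectedK = part$k, partitionExact = exact,
                   coclusterAccuracy = acc)
    })
    do.call(rbind, rows)
}

#' Null calibration study for the signed one-tail p-values
#'
#' Simulates a ligand whose condition is identical in distribution to the
#' basal control, recomputes the mixed-model signed p-value for the
#' HSC-enriched population per replicate, and reports the directional
#' rejection rates at \code{alpha} (each is the one-tail test's type-I
#' error; their sum is the rate of any significant arrow).
#'
#' @param nRep replicates (default 1000)
#' @param alpha significance threshold
#' @param baseSeed first replicate seed
#' @return list: \code{up}, \code{down} (directional rejection rates),
#'   \code{any} (their sum), \code{pvalues} (the signed p-values)
#' @export
typeIErrorStudy <- function(nRep = 1000L, alpha = 0.02,
                            baseSeed = 20000L) {
    p <- vapply(seq_len(nRep), function(i) {
        cnt <- generateInvitroCounts(c(LIGNULL = "neutral"),
                                     seed = as.integer(baseSeed + i))
        suppressWarnings(
            signedPValues(cnt, "LIGNULL")[["hsc_enriched"]])
    }, numeric(1))
    up <- mean(p > 0 & p <= alpha)
    down <- mean(p < 0 & -p <= alpha)
    list(up = up, down = down, any = up + down, pvalues = p)
}
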