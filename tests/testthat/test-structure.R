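test_that("identical ligand sets cluster together at distance zero", {
    A <- rbind(c1 = c(1, 1, 0, 0), c2 = c(1, 1, 0, 0),
               c3 = c(0, 0, 1, 1), c4 = c(0, 0, 1, 0))
    colnames(A) <- paste0("L", 1:4)
    part <- clusterProduction(A, kRange = 2)
    expect_equal(part$assignment[["c1"]], part$assignment[["c2"]])
    expect_false(part$assignment[["c1"]] == part$assignment[["c3"]])
})

test_that("planted disjoint blocks select the planted k with silhouette", {
    # 4 blocks of cells with mutually exclusive ligand sets
    blocks <- rep(1:4, times = c(4, 3, 3, 2))
    A <- matrix(0, 12, 20,
                dimnames = list(paste0("c", 1:12), paste0("L", 1:20)))
    for (i in seq_len(12))
        A[i, (blocks[i] - 1) * 5 + 1:5] <- 1
    part <- clusterProduction(A, kRange = 2:6)
    expect_equal(part$k, 4L)
    expect_equal(labelMatchAccuracy(part$assignment,
                                    setNames(blocks, rownames(A))), 1)
    expect_true(mean(part$silhouette) > 0.9)
})

test_that("fully overlapping ligand sets yield a no-modularity verdict", {
    A <- matrix(1, 6, 10, dimnames = list(paste0("c", 1:6),
                                          paste0("L", 1:10)))
    A[, 10] <- c(1, 1, 1, 1, 1, 0)   # minimal variation to avoid all-0 cut
    expect_warning(part <- clusterProduction(A, kRange = 2:4), NA)
    expect_lt(mean(part$meanSilhouettePerK$meanSilhouette), 0.3)
})

test_that("empty-empty cell pairs get distance zero with a warning", {
    A <- rbind(c1 = c(1, 1, 0), c2 = c(0, 0, 0), c3 = c(0, 0, 0))
    colnames(A) <- paste0("L", 1:3)
    expect_warning(part <- clusterProduction(A, kRange = 2), "empty")
    expect_equal(part$assignment[["c2"]], part$assignment[["c3"]])
})

test_that("Jaccard distances satisfy the triangle inequality", {
    set.seed(5)
    for (rep in 1:20) {
        A <- matrix(rbinom(5 * 8, 1, 0.5), 5, 8)
        rownames(A) <- paste0("c", 1:5)
        d <- as.matrix(suppressWarnings(hemaCCC:::.jaccardDist(A)))
        for (i in 1:5) for (j in 1:5) for (k in 1:5)
            expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    }
})

test_that("exact block-diagonal matrices co-cluster into their blocks", {
    B <- matrix(0, 8, 6, dimnames = list(paste0("L", 1:8),
                                         paste0("c", 1:6)))
    B[1:4, 1:3] <- matrix(c(2, 1, 1, 1, 2, 1, 1, 1, 2, 1, 1, 1), 4, 3)
    B[5:8, 4:6] <- matrix(c(1, 2, 1, 2, 1, 1, 1, 1, 3, 1, 2, 1), 4, 3)
    cc <- coclusterBinding(B, k = 2)
    truth <- setNames(rep(1:2, each = 4), rownames(B))
    truthC <- setNames(rep(1:2, each = 3), colnames(B))
    expect_equal(labelMatchAccuracy(cc$rowAssignment, truth), 1)
    expect_equal(labelMatchAccuracy(cc$colAssignment, truthC), 1)
})

test_that("planted 4-block matrices with 5% noise are recovered >= 95%", {
    accs <- vapply(1:20, function(s) {
        set.seed(900 + s)
        blocksR <- rep(1:4, each = 10)
        blocksC <- rep(1:4, each = 3)
        B <- matrix(0, 40, 12)
        for (i in seq_along(blocksR)) for (j in seq_along(blocksC))
            if (blocksR[i] == blocksC[j]) B[i, j] <- 1 + rpois(1, 1)
        # 5% off-block noise
        off <- which(B == 0)
        B[sample(off, round(0.05 * length(off)))] <- 1
        dimnames(B) <- list(paste0("L", 1:40), paste0("c", 1:12))
        keep <- rowSums(B) > 0
        cc <- coclusterBinding(B[keep, ], k = 4)
        truth <- setNames(c(blocksR[keep], blocksC),
                          c(rownames(B)[keep], colnames(B)))
        labelMatchAccuracy(c(cc$rowAssignment, cc$colAssignment), truth)
    }, numeric(1))
    expect_gte(mean(accs), 0.95)
})

test_that("co-clustering is invariant to row/column permutation", {
    set.seed(77)
    B <- matrix(rpois(15 * 6, 2) * rbinom(15 * 6, 1, 0.5) + 1, 15, 6,
                dimnames = list(paste0("L", 1:15), paste0("c", 1:6)))
    cc1 <- coclusterBinding(B, k = 3)
    pr <- sample(15); pc <- sample(6)
    cc2 <- coclusterBinding(B[pr, pc], k = 3)
    expect_equal(labelMatchAccuracy(cc2$rowAssignment,
                                    cc1$rowAssignment), 1)
    expect_equal(labelMatchAccuracy(cc2$colAssignment,
                                    cc1$colAssignment), 1)
})

test_that("degenerate all-ones matrices show near-equal singular values", {
    B <- matrix(1, 6, 6, dimnames = list(paste0("L", 1:6),
                                         paste0("c", 1:6)))
    cc <- coclusterBinding(B, k = 2)
    # all non-leading singular values collapse: no separable structure
    expect_lt(cc$singularValues[2], 1e-8)
    expect_error(coclusterBinding(rbind(B, L7 = rep(0, 6)), k = 2), "L7")
})

test_that("module-overlap comparison reproduces printed-vector behaviour", {
    # identity: S == T gives p = 1 under the pooled test
    same <- list(m1 = c("a", "b"), m2 = c("b", "c"), m3 = c("a", "c"))
    r <- compareModuleOverlap(same, same, variant = "pooled")
    expect_equal(r$S, r$T)
    expect_equal(r$p, 1)
    expect_error(compareModuleOverlap(list(m1 = "a"), same), ">= 2")
    # Welch t on fixed vectors, against an independent arithmetic oracle
    S <- c(9, 13, 10, 12, 12, 17); T_ <- c(75, 75, 69)
    tWelch <- (mean(S) - mean(T_)) /
        sqrt(var(S) / length(S) + var(T_) / length(T_))
    r2 <- overlapTTest(S, T_, variant = "welch")
    expect_equal(r2$t, tWelch)
})

test_that("module ligand sets union production columns per module", {
    A <- rbind(c1 = c(1, 0, 1), c2 = c(0, 1, 0), c3 = c(0, 0, 1))
    colnames(A) <- c("L1", "L2", "L3")
    sets <- moduleLigandSets(A, c(c1 = 1, c2 = 2, c3 = 1))
    expect_setequal(sets$module1, c("L1", "L3"))
    expect_identical(sets$module2, "L2")
})

test_that("bootstrap confidence recovers stable planted modules", {
    blocks <- rep(1:3, each = 3)
    A <- matrix(0, 9, 15, dimnames = list(paste0("c", 1:9),
                                          paste0("L", 1:15)))
    for (i in seq_len(9)) A[i, (blocks[i] - 1) * 5 + 1:5] <- 1
    part <- clusterProduction(A, kRange = 3)
    conf <- bootstrapClusterConfidence(A, part, nBoot = 50L, seed = 2L)
    expect_true(all(conf > 0.8))
})
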