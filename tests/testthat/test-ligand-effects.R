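test_that("every arrow triple maps to exactly one category", {
    arrows <- c("0", "+", "-")
    toP <- c("0" = 0.5, "+" = 0.01, "-" = -0.01)
    combos <- expand.grid(a = arrows, b = arrows, c = arrows,
                          stringsAsFactors = FALSE)
    cats <- apply(combos, 1, function(r)
        classifyLigand(toP[r], alpha = 0.02))
    expect_length(cats, 27L)
    expect_true(all(cats %in% functionalCategories()))
    # 17 mapped rows, 10 indeterminate
    expect_equal(sum(cats != "indeterminate"), 17L)
    tab <- table(cats)
    expect_equal(unname(tab["neutral"]), 1L)
    expect_equal(unname(tab["quiescence_induction"]), 2L)
    expect_equal(unname(tab["self_renewal_induction"]), 1L)
    expect_equal(unname(tab["differentiation_induction"]), 4L)
    expect_equal(unname(tab["proliferation_induction"]), 5L)
    expect_equal(unname(tab["proliferation_inhibition"]), 4L)
})

test_that("classifier reproduces the documented dose series", {
    # no significant change on any population -> neutral
    expect_equal(classifyLigand(c(0.2747, 0.2642, 0.3721), 0.02),
                 "neutral")
    # increase in the stem-cell-enriched population only -> self-renewal
    expect_equal(classifyLigand(c(0.0036, 0.30, 0.50), 0.02),
                 "self_renewal_induction")
    # decrease in all three populations -> proliferation inhibition
    expect_equal(classifyLigand(c(-0.0007, -0.0094, -0.0207), 0.05),
                 "proliferation_inhibition")
    # the same triple at stricter alpha keeps only two arrows
    expect_equal(classifyLigand(c(-0.0007, -0.0094, -0.0207), 0.01),
                 "proliferation_inhibition")   # "down down 0" row
    expect_warning(classifyLigand(c(0.5, 0.5, 0.5), alpha = 0.03),
                   "non-conventional")
})

test_that("arrows are monotone in alpha", {
    set.seed(3)
    for (i in 1:50) {
        p <- runif(3, 0, 1) * sample(c(-1, 1), 3, replace = TRUE)
        arrowsAt <- function(a) vapply(p, function(x)
            if (abs(x) <= a) sign(x) else 0, numeric(1))
        a1 <- arrowsAt(0.01); a5 <- arrowsAt(0.05)
        # an arrow present at strict alpha persists at looser alpha
        expect_true(all(a1 == 0 | a1 == a5))
    }
})

test_that("dose-series reporting picks the most effective dose", {
    doseP <- list("1" = c(0.2747, 0.2642, 0.3721),
                  "10" = c(0.0036, 0.30, 0.50),
                  "100" = c(-0.0007, -0.0094, -0.0207))
    r <- classifyDoseSeries(doseP, alpha = 0.02)
    expect_equal(r$dose, 100)   # smallest |p| anywhere
    expect_equal(r$category, "proliferation_inhibition")
    # all-null series falls back to the highest dose
    nullP <- list("1" = c(0.4, 0.5, 0.6), "10" = c(0.3, 0.7, 0.9))
    r2 <- classifyDoseSeries(nullP, alpha = 0.02)
    expect_equal(r2$dose, 10)
    expect_equal(r2$category, "neutral")
    expect_false(r2$contextSensitive)
})

test_that("signed p-values recover planted directions with power", {
    hits <- vapply(1:40, function(i) {
        cnt <- generateInvitroCounts(c(LX = "self_renewal_induction"),
                                     effect = 0.41,  # +50% on log scale
                                     seed = 3000L + i)
        sp <- suppressWarnings(signedPValues(cnt, "LX"))
        sp[["hsc_enriched"]] > 0
    }, logical(1))
    expect_gte(mean(hits), 0.95)
})

test_that("category recovery works for a strong planted effect", {
    cnt <- generateInvitroCounts(c(LX = "self_renewal_induction"),
                                 effect = 0.8, seed = 77L)
    sp <- signedPValues(cnt, "LX")
    expect_equal(classifyLigand(sp, 0.02), "self_renewal_induction")
    cnt2 <- generateInvitroCounts(c(LY = "proliferation_inhibition"),
                                  effect = 0.8, seed = 78L)
    expect_equal(classifyLigand(signedPValues(cnt2, "LY"), 0.02),
                 "proliferation_inhibition")
})

test_that("zero experiment variance agrees with the fixed-effect fit", {
    cnt <- generateInvitroCounts(c(LX = "neutral"), experimentSd = 0,
                                 nExperiments = 4L, replicates = 4L,
                                 seed = 55L)
    spMixed <- suppressWarnings(signedPValues(cnt, "LX"))
    # plain linear model on the same data
    sub <- cnt[cnt$condition %in% c("LX", "basal_control"), ]
    y <- log(sub$n_hsc_enriched + 1)
    cond <- factor(ifelse(sub$condition == "LX", "ligand", "control"),
                   levels = c("control", "ligand"))
    sm <- summary(lm(y ~ cond))$coefficients
    pLm <- sign(sm[2, 1]) * sm[2, 4] / 2
    expect_equal(spMixed[["hsc_enriched"]], pLm, tolerance = 0.02)
})

test_that("single-experiment data degrade to a fixed-effect comparison", {
    cnt <- generateInvitroCounts(c(LX = "neutral"), seed = 60L)
    cnt <- cnt[cnt$experiment == "E1", ]
    expect_warning(sp <- signedPValues(cnt, "LX"), "falling back")
    expect_true(all(abs(sp) > 0 & abs(sp) <= 1))
    expect_error(signedPValues(cnt, "MISSING"), "not found")
})

test_that("binomial capacity test matches exhaustive enumeration", {
    # brute force over all 2^n outcomes for small n
    for (n in c(4, 8, 12)) {
        outcomes <- expand.grid(rep(list(0:1), n))
        k <- rowSums(outcomes)
        for (kk in c(0, n %/% 2, n)) {
            r <- predictionCapacityTest(n, kk, 0.5)
            expect_equal(r$point, mean(k == kk), tolerance = 1e-12)
            expect_equal(r$tail, mean(k >= kk), tolerance = 1e-12)
        }
    }
    r <- predictionCapacityTest(4, 4, 0.5)
    expect_equal(r$point, 0.0625)
    expect_equal(r$tail, 0.0625)
    expect_error(predictionCapacityTest(4, 5, 0.5), "nEffective")
})

test_that("hypergeometric Z agrees with enumerated standardization", {
    set.seed(19)
    for (rep in 1:40) {
        N <- sample(5:50, 1)
        m <- sample(1:(N - 1), 1)
        n <- sample(1:(N - 1), 1)
        k <- sample(max(0, n + m - N):min(n, m), 1)
        expect_equal(hypergeometricZ(N, m, n, k), enumHyperZ(N, m, n, k),
                     tolerance = 1e-10)
    }
    # mean case: observed equals expectation -> Z = 0
    expect_equal(hypergeometricZ(20, 10, 6, 3), 0)
    expect_warning(hypergeometricZ(10, 10, 4, 4), "degenerate")
})

test_that("celltype enrichment skips empty producers and flags at 1.15", {
    calls <- makeCalls(
        ligands = list(HSCe = c("L1", "L2"), T2 = c("L3", "L4"),
                       T3 = character(0)),
        receptors = list(HSCe = c("R1", "R2", "R3", "R4"),
                         T2 = character(0), T3 = "R1"))
    lr <- LRInteractionTable(ligand = paste0("L", 1:4),
                             receptor = paste0("R", 1:4))
    net <- buildNetwork(calls, lr, includeOthers = FALSE)
    cats <- c(L1 = "neutral", L2 = "self_renewal_induction",
              L3 = "self_renewal_induction", L4 = "indeterminate")
    expect_warning(z <- celltypeFunctionalEnrichment(net, cats, "HSCe"),
                   "T3")
    # indeterminate ligands fall out of the universe
    expect_equal(unique(z$N), 3L)
    expect_true(all(c("HSCe", "T2") %in% z$cell))
    expect_true(is.logical(z$enriched))
})

test_that("feedback network weights follow the three modes", {
    calls <- makeCalls(
        ligands = list(HSCe = "L1", Neut = "L2", T3 = character(0)),
        receptors = list(HSCe = c("R1", "R2", "R3"),
                         Neut = character(0), T3 = character(0)))
    lr <- LRInteractionTable(ligand = c("L1", "L1", "L2"),
                             receptor = c("R1", "R2", "R3"))
    net <- buildNetwork(calls, lr, includeOthers = FALSE)
    cats <- c(L1 = "self_renewal_induction",
              L2 = "proliferation_inhibition")
    rl <- c(R1 = 2, R2 = 3, R3 = 4)
    fb <- buildFeedbackNetwork(net, lr, cats, rl, mode = "receptor")
    expect_equal(fb$weight[fb$cell == "HSCe"], 5)   # R1 + R2
    expect_equal(fb$weight[fb$cell == "Neut"], 4)   # R3
    f <- c(HSCe = 0.1, Neut = 0.8, T3 = 0.1)
    fbF <- buildFeedbackNetwork(net, lr, cats, rl, mode = "frequency",
                                freqs = f)
    expect_equal(fbF$weight[fbF$cell == "HSCe"], 0.5)
    # doubling a frequency doubles that cell's weights
    f2 <- f; f2["HSCe"] <- 0.2
    fb2 <- buildFeedbackNetwork(net, lr, cats, rl, mode = "frequency",
                                freqs = f2)
    expect_equal(fb2$weight[fb2$cell == "HSCe"],
                 2 * fbF$weight[fbF$cell == "HSCe"])
    # peripheral compartment factor multiplies on top of frequency
    fbC <- buildFeedbackNetwork(net, lr, cats, rl, mode = "compartment",
                                freqs = f,
                                compartmentWeights = c(Neut = 0.1))
    expect_equal(fbC$weight[fbC$cell == "Neut"],
                 0.1 * fbF$weight[fbF$cell == "Neut"])
    expect_equal(fbC$weight[fbC$cell == "HSCe"],
                 fbF$weight[fbF$cell == "HSCe"])
    expect_error(buildFeedbackNetwork(net, lr, cats, rl,
                                      mode = "frequency",
                                      freqs = c(HSCe = 1)), "Neut")
})

test_that("Others is dropped from frequency-weighted feedback modes", {
    calls <- makeCalls(ligands = list(HSCe = character(0)),
                       receptors = list(HSCe = "R1"))
    lr <- LRInteractionTable(ligand = "L1", receptor = "R1")
    net <- buildNetwork(calls, lr, includeOthers = TRUE)
    cats <- c(L1 = "neutral")
    rl <- c(R1 = 1)
    fbR <- buildFeedbackNetwork(net, lr, cats, rl, mode = "receptor")
    expect_true("Others" %in% fbR$cell)
    fbF <- buildFeedbackNetwork(net, lr, cats, rl, mode = "frequency",
                                freqs = c(HSCe = 1))
    expect_false("Others" %in% fbF$cell)
})

test_that("category permutation test sees obvious concentration", {
    cats <- setNames(rep(c("a", "b", "c", "d"), each = 6),
                     paste0("L", 1:24))
    r <- categoryPermutationTest(cats, paste0("L", 1:5), nPerm = 500L)
    expect_equal(r$observed, 5L)
    expect_lt(r$p, 0.05)
})
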