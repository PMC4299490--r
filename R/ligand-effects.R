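# The 17-row arrow decision table mapping the direction triple over
# (HSC-enriched, progenitor, mature) to a functional category. "0" = no
# change vs the basal control, "+" = significant increase, "-" =
# significant decrease. Triples not listed are indeterminate.
.decisionTable <- c(
    "0 0 0" = "neutral",
    "0 0 -" = "quiescence_induction",
    "0 - 0" = "quiescence_induction",
    "+ 0 0" = "self_renewal_induction",
    "0 + 0" = "differentiation_induction",
    "0 0 +" = "differentiation_induction",
    "0 + +" = "differentiation_induction",
    "- - +" = "differentiation_induction",
    "+ + 0" = "proliferation_induction",
    "+ + -" = "proliferation_induction",
    "+ + +" = "proliferation_induction",
    "+ 0 +" = "proliferation_induction",
    "+ - +" = "proliferation_induction",
    "- - -" = "proliferation_inhibition",
    "- - 0" = "proliferation_inhibition",
    "- 0 -" = "proliferation_inhibition",
    "- 0 0" = "proliferation_inhibition")

#' Functional category labels
#'
#' @return character vector of the recognised categories (including
#'   \code{"indeterminate"} for arrow triples outside the decision table)
#' @export
functionalCategories <- function() {
    unique(c(unname(.decisionTable), "indeterminate"))
}

# Fit one population's mixed model and return the signed one-tail p.
.signedPOne <- function(df) {
    # log(count + 1): fold-change framing; +1 guards empty wells
    df$y <- log(df$count + 1)
    df$cond <- factor(df$cond, levels = c("control", "ligand"))
    nExp <- length(unique(df$experiment))
    est <- p2 <- NULL
    if (nExp >= 2) {
        fit <- tryCatch(
            nlme::lme(y ~ cond, random = ~ 1 | experiment, data = df),
            error = function(e) NULL)
        if (!is.null(fit)) {
            tt <- summary(fit)$tTable
            est <- tt["condligand", "Value"]
            p2 <- tt["condligand", "p-value"]
        }
    }
    if (is.null(est)) {
        warning("mixed model unavailable (", nExp, " experiment(s)); ",
                "falling back to a fixed-effect comparison")
        fit <- stats::lm(y ~ cond, data = df)
        sm <- summary(fit)$coefficients
        est <- sm["condligand", "Estimate"]
        p2 <- sm["condligand", "Pr(>|t|)"]
    }
    p1 <- p2 / 2
    if (p1 <= 0) p1 <- .Machine$double.xmin
    sign(ifelse(est == 0, 1, est)) * p1
}

#' Signed one-tail p-values for a ligand condition
#'
#' For each of the three output populations (HSC-enriched, progenitor,
#' mature), fits a linear mixed model of log(count + 1) on a
#' condition indicator (ligand vs basal control) with a per-experiment
#' random intercept, halves the two-tail p-value and attaches the sign of
#' the estimated condition effect: positive means the ligand raised the
#' population relative to the basal control. Nominal p-values; no
#' multiple-testing correction (the priority is not missing effective
#' ligands).
#'
#' @param counts data.frame as produced by
#'   \code{\link{generateInvitroCounts}} (columns \code{experiment},
#'   \code{condition}, \code{n_hsc_enriched}, \code{n_progenitor},
#'   \code{n_mature})
#' @param ligandCondition the condition label to compare against
#'   \code{controlCondition}
#' @param controlCondition label of the basal control rows (default
#'   \code{"basal_control"})
#' @return named numeric triple of signed one-tail p-values
#'   (\code{hsc_enriched}, \code{progenitor}, \code{mature})
#' @export
signedPValues <- function(counts, ligandCondition,
                          controlCondition = "basal_control") {
    need <- c("experiment", "condition", "n_hsc_enriched",
              "n_progenitor", "n_mature")
    if (!all(need %in% colnames(counts)))
        stop("counts must have columns ",
             paste(need, collapse = ", "))
    sub <- counts[counts$condition %in% c(ligandCondition,
                                          controlCondition), ,
                  drop = FALSE]
    if (!any(sub$condition == ligandCondition))
        stop("condition not found: ", ligandCondition)
    if (!any(sub$condition == controlCondition))
        stop("control condition not found: ", controlCondition)
    cond <- ifelse(sub$condition == ligandCondition, "ligand", "control")
    pops <- c(hsc_enriched = "n_hsc_enriched",
              progenitor = "n_progenitor", mature = "n_mature")
    vapply(pops, function(col) {
        .signedPOne(data.frame(experiment = sub$experiment, cond = cond,
                               count = sub[[col]]))
    }, numeric(1))
}

#' Classify a ligand from its signed p-value triple
#'
#' Each signed one-tail p-value maps to an arrow: "+" when positive with
#' |p| <= alpha, "-" when negative with |p| <= alpha, "0" otherwise. The
#' arrow triple over (HSC-enriched, progenitor, mature) is looked up in
#' the 17-row decision table; triples outside the table return
#' \code{"indeterminate"}. Confidence conventions: alpha 0.01 = high,
#' 0.02 = intermediate, 0.05 = low.
#'
#' @param signedP numeric triple of signed one-tail p-values
#' @param alpha significance threshold (0.01 / 0.02 / 0.05 are the
#'   conventional levels; other values are accepted with a warning)
#' @return a single category string
#' @export
classifyLigand <- function(signedP, alpha = 0.02) {
    signedP <- as.numeric(signedP)
    if (length(signedP) != 3L || anyNA(signedP))
        stop("signedP must be a complete numeric triple")
    if (!alpha %in% c(0.01, 0.02, 0.05))
        warning("non-conventional alpha ", alpha,
                " (conventional: 0.01, 0.02, 0.05)")
    arrows <- vapply(signedP, function(p) {
        if (abs(p) <= alpha) if (p > 0) "+" else "-" else "0"
    }, character(1))
    key <- paste(arrows, collapse = " ")
    if (key %in% names(.decisionTable)) unname(.decisionTable[[key]])
    else "indeterminate"
}

#' Classify a ligand across its dose series
#'
#' The category is taken at the most effective dose: the dose with the
#' smallest |signed p| on any population (ties broken toward the lower
#' dose). If no dose has a significant effect at \code{alpha}, the
#' highest dose's record is reported. Ligands whose category flips across
#' the conventional alpha levels are flagged context-sensitive.
#'
#' @param doseP named list: dose (coercible to numeric) -> signed p
#'   triple
#' @param alpha threshold for the reported categorization
#' @return list: \code{category}, \code{dose} (the reported dose),
#'   \code{contextSensitive} (TRUE if the category at the reported dose
#'   differs across alpha in 0.01/0.02/0.05)
#' @export
classifyDoseSeries <- function(doseP, alpha = 0.02) {
    doses <- as.numeric(names(doseP))
    if (anyNA(doses)) stop("doseP must be named by numeric doses")
    minAbs <- vapply(doseP, function(p) min(abs(p)), numeric(1))
    anySig <- minAbs <= alpha
    pick <- if (any(anySig)) {
        cand <- which(anySig)
        cand[order(minAbs[cand], doses[cand])][1]
    } else which.max(doses)
    p <- doseP[[pick]]
    cats <- vapply(c(0.01, 0.02, 0.05), function(a)
        classifyLigand(p, a), character(1))
    list(category = classifyLigand(p, alpha), dose = doses[pick],
         contextSensitive = length(unique(cats)) > 1L)
}

#' Binomial prediction-capacity test
#'
#' Models ligand selection as a binomial process: with \code{nTested}
#' ligands tested and a success probability \code{p0} that a selected
#' ligand is functional, returns the point probability of exactly
#' \code{nEffective} effective ligands, the upper-tail probability
#' P(X >= nEffective), and the expected count.
#'
#' @param nTested number of tested ligands
#' @param nEffective number found effective
#' @param p0 success probability (default 0.5)
#' @return list: \code{point}, \code{tail}, \code{expected}
#' @export
predictionCapacityTest <- function(nTested, nEffective, p0 = 0.5) {
    if (nEffective < 0 || nEffective > nTested)
        stop("nEffective must lie in [0, nTested]")
    if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
    list(point = stats::dbinom(nEffective, nTested, p0),
         tail = stats::pbinom(nEffective - 1, nTested, p0,
                              lower.tail = FALSE),
         expected = nTested * p0)
}

#' Hypergeometric enrichment Z-score
#'
#' Standardizes the observed overlap k against the hypergeometric mean
#' and variance: drawing n of N ligands when m belong to the function
#' group, \deqn{Z = \frac{k - n m / N}
#'   {\sqrt{n (m/N)(1 - m/N)(N - n)/(N - 1)}}}
#' The conventional enrichment call is Z > 1.15.
#'
#' @param N universe size; @param m group size; @param n draw size;
#' @param k observed overlap
#' @return the Z-score (NA with a warning when undefined)
#' @export
hypergeometricZ <- function(N, m, n, k) {
    v <- if (N <= 1) 0
         else n * (m / N) * (1 - m / N) * (N - n) / (N - 1)
    if (!is.finite(v) || v <= 0) {
        warning("degenerate hypergeometric (zero variance)")
        return(NA_real_)
    }
    (k - n * m / N) / sqrt(v)
}

#' Per-cell-type functional enrichment of targeted ligands
#'
#' For each cell node of the network and each functional category,
#' standardizes the overlap between the cell's produced target-binding
#' ligands and the category's ligands by the hypergeometric Z-score. The
#' universe N is the set of categorized ligands that both bind the target
#' cell and are produced by some cell node. Indeterminate ligands are
#' excluded. Cells producing no categorized ligand are skipped with a
#' warning.
#'
#' @param net a \linkS4class{CCCNetwork}
#' @param categories named character vector ligand -> category
#' @param targetCell the receiving cell type (default \code{"HSCe"})
#' @param zThreshold enrichment call threshold (default 1.15)
#' @return data.frame (cell, category, N, m, n, k, Z, enriched)
#' @export
celltypeFunctionalEnrichment <- function(net, categories,
                                         targetCell = "HSCe",
                                         zThreshold = 1.15) {
    stopifnot(is(net, "CCCNetwork"))
    if (!targetCell %in% net@cellNodes)
        stop("target cell not in the network: ", targetCell)
    categories <- categories[categories != "indeterminate"]
    targeting <- net@ligandNodes[net@binding[, targetCell] >= 1]
    universe <- intersect(targeting, names(categories))
    universe <- universe[colSums(
        net@production[, universe, drop = FALSE]) > 0]
    N <- length(universe)
    if (N == 0) stop("no categorized ligand targets ", targetCell)
    cats <- unique(categories[universe])
    rows <- list()
    for (cell in net@cellNodes) {
        mine <- universe[net@production[cell, universe] == 1]
        n <- length(mine)
        if (n == 0) {
            warning("cell producing no categorized targeting ligand ",
                    "skipped: ", cell)
            next
        }
        for (cat in cats) {
            grp <- universe[categories[universe] == cat]
            m <- length(grp)
            k <- length(intersect(mine, grp))
            z <- suppressWarnings(hypergeometricZ(N, m, n, k))
            rows[[length(rows) + 1L]] <- data.frame(
                cell = cell, category = cat, N = N, m = m, n = n, k = k,
                Z = z, enriched = !is.na(z) && z > zThreshold)
        }
    }
    do.call(rbind, rows)
}

#' Build the weighted feedback network toward the target cell
#'
#' Edges run cell -> functional category -> target cell. In receptor mode
#' the weight of the edge from cell i through category c is the sum, over
#' i's produced ligands of category c, of the target cell's expression
#' levels summed across the ligand's receptor species. Frequency mode
#' multiplies each cell's weights by its frequency; compartment mode
#' additionally multiplies by a per-cell compartment reach factor
#' (default 0.1 for peripheral cells, 1 otherwise). The "Others" node has
#' no frequency and is dropped in frequency/compartment modes.
#'
#' @param net a \linkS4class{CCCNetwork}
#' @param lr an \linkS4class{LRInteractionTable}
#' @param categories named character vector ligand -> category
#'   (indeterminate excluded)
#' @param receptorLevels named numeric: target-cell expression level per
#'   receptor gene
#' @param mode \code{"receptor"}, \code{"frequency"} or
#'   \code{"compartment"}
#' @param freqs named frequency vector (required for frequency and
#'   compartment modes; must cover every modeled producing cell)
#' @param compartmentWeights named per-cell reach factor for compartment
#'   mode (cells absent from the vector default to 1)
#' @param targetCell receiving cell (default \code{"HSCe"})
#' @return data.frame (cell, category, weight, mode), zero-weight edges
#'   dropped
#' @export
buildFeedbackNetwork <- function(net, lr, categories, receptorLevels,
                                 mode = c("receptor", "frequency",
                                          "compartment"),
                                 freqs = NULL, compartmentWeights = NULL,
                                 targetCell = "HSCe") {
    stopifnot(is(net, "CCCNetwork"), is(lr, "LRInteractionTable"))
    mode <- match.arg(mode)
    categories <- categories[categories != "indeterminate"]
    p <- as.data.frame(lr@pairs)
    cells <- net@cellNodes
    if (mode != "receptor") {
        cells <- setdiff(cells, "Others")   # no frequency information
        if (is.null(freqs))
            stop("freqs is required in ", mode, " mode")
        missing <- setdiff(
            cells[rowSums(net@production[cells, , drop = FALSE]) > 0],
            names(freqs))
        if (length(missing))
            stop("missing frequency for: ",
                 paste(missing, collapse = ", "))
    }
    ligW <- vapply(net@ligandNodes, function(lg) {
        sum(receptorLevels[p$receptor[p$ligand == lg]], na.rm = TRUE)
    }, numeric(1))
    rows <- list()
    for (cell in cells) {
        mine <- net@ligandNodes[net@production[cell, ] == 1]
        mine <- intersect(mine, names(categories))
        if (!length(mine)) next
        fac <- 1
        if (mode %in% c("frequency", "compartment"))
            fac <- fac * unname(freqs[cell])
        if (mode == "compartment" && !is.null(compartmentWeights) &&
            cell %in% names(compartmentWeights))
            fac <- fac * unname(compartmentWeights[cell])
        for (cat in unique(categories[mine])) {
            w <- fac * sum(ligW[mine[categories[mine] == cat]])
            if (w > 0)
                rows[[length(rows) + 1L]] <- data.frame(
                    cell = cell, category = cat, weight = w, mode = mode)
        }
    }
    if (!length(rows))
        return(data.frame(cell = character(0), category = character(0),
                          weight = numeric(0), mode = character(0)))
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Export a feedback network
#'
#' GraphML via igraph (cell and category nodes, weighted edges carrying
#' the mode attribute) or long-format TSV.
#'
#' @param feedback data.frame from \code{\link{buildFeedbackNetwork}}
#' @param path destination path
#' @param targetCell name of the receiving node added to the graph
#' @export
writeFeedbackGraphML <- function(feedback, path, targetCell = "HSCe") {
    cats <- unique(feedback$category)
    g <- igraph::make_empty_graph(directed = TRUE) +
        igraph::vertices(unique(feedback$cell), kind = "cell") +
        igraph::vertices(cats, kind = "category") +
        igraph::vertices(paste0(targetCell, "_target"), kind = "target")
    for (i in seq_len(nrow(feedback)))
        g <- g + igraph::edges(c(feedback$cell[i], feedback$category[i]),
                               weight = feedback$weight[i],
                               mode = feedback$mode[i])
    for (cat in cats)
        g <- g + igraph::edges(c(cat, paste0(targetCell, "_target")),
                               weight = 1, mode = feedback$mode[1])
    igraph::write_graph(g, path, format = "graphml")
    invisible(path)
}

#' @rdname writeFeedbackGraphML
#' @export
writeFeedbackEdgeList <- function(feedback, path) writeTSV(feedback, path)

#' Permutation test for category-label concentration
#'
#' A generic label-shuffling test: given per-item categories and a
#' response subset (e.g. items sharing a downstream regulator), shuffles
#' the categorization and reports the fraction of permutations in which a
#' random category assignment concentrates the subset in one category at
#' least as strongly as observed (max within-category count).
#'
#' @param categories named character vector item -> category
#' @param subset character vector of item names
#' @param nPerm number of permutations (default 10000)
#' @param seed RNG seed
#' @return list: \code{observed} (max within-category count),
#'   \code{p} (permutation p-value)
#' @export
categoryPermutationTest <- function(categories, subset, nPerm = 10000L,
                                    seed = 1L) {
    subset <- intersect(subset, names(categories))
    if (!length(subset)) stop("subset has no categorized items")
    obs <- max(table(categories[subset]))
    withSeed(seed, {
        hits <- 0L
        for (b in seq_len(nPerm)) {
            perm <- stats::setNames(sample(categories), names(categories))
            if (max(table(perm[subset])) >= obs) hits <- hits + 1L
        }
        list(observed = obs, p = hits / nPerm)
    })
}
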