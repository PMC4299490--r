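#' Simulate which ligands reach the stem cell (OR-gate Monte Carlo)
#'
#' Per simulation and compartment, an independent Bernoulli indicator is
#' drawn for every ligand of the compartment's set with the compartment's
#' reach probability; the reachable set is the union (OR) across
#' compartments, so a ligand produced in two compartments reaches if it
#' reaches via either. An all-or-none variant draws a single indicator per
#' compartment per simulation.
#'
#' @param model a \linkS4class{CompartmentModel}
#' @param perCompartment if TRUE, one Bernoulli draw gates a compartment's
#'   whole ligand set (all-or-none); default FALSE (per-ligand draws)
#' @return list of character vectors, one reachable ligand set per
#'   simulation; deterministic given the model seed
#' @export
simulateReachableLigands <- function(model, perCompartment = FALSE) {
    stopifnot(is(model, "CompartmentModel"))
    withSeed(model@seed, {
        lapply(seq_len(model@nSims), function(s) {
            reached <- character(0)
            for (cp in model@compartments) {
                lig <- model@ligandSets[[cp]]
                if (!length(lig)) next
                p <- model@reachProb[[cp]]
                if (perCompartment) {
                    if (stats::runif(1) <= p) reached <- c(reached, lig)
                } else {
                    x <- stats::runif(length(lig)) <= p
                    reached <- c(reached, lig[x])
                }
            }
            unique(reached)
        })
    })
}

# Closed-form reach probability per ligand: 1 - prod over compartments
# holding the ligand of (1 - reach probability).
.reachProbability <- function(model) {
    lig <- unique(unlist(model@ligandSets))
    miss <- vapply(lig, function(lg) {
        prod(vapply(model@compartments, function(cp)
            if (lg %in% model@ligandSets[[cp]])
                1 - model@reachProb[[cp]] else 1, numeric(1)))
    }, numeric(1))
    1 - miss
}

#' Enrichment of reachable ligands in biological-process sets
#'
#' For a process with ligand set B, enrichment per simulation is
#' \code{E = n(reachable AND B) / n(B)}; the mean over simulations is
#' reported. The closed-form expectation (sum over B of each ligand's
#' reach probability, divided by n(B)) is returned alongside as a check.
#' Significance of each process is assessed against a permutation null:
#' ligand labels are shuffled within the ligand universe and the process
#' flagged enriched when its mean E exceeds the null's 95th percentile.
#'
#' @param model a \linkS4class{CompartmentModel}
#' @param annotations named list: process -> ligand set. Ligands outside
#'   the model's ligand universe count in n(B) but can never be reached
#'   (reported via a message)
#' @param nPerm permutations for the null (0 disables the significance
#'   flag; default 1000)
#' @param permSeed seed for the permutation null
#' @return data.frame (process, n, meanE, expectedE, null95, enriched)
#' @export
enrichmentProfile <- function(model, annotations, nPerm = 1000L,
                              permSeed = 1L) {
    stopifnot(is(model, "CompartmentModel"))
    if (!length(annotations) || any(lengths(annotations) == 0L))
        stop("every annotation set must be non-empty")
    universe <- unique(unlist(model@ligandSets))
    outside <- setdiff(unique(unlist(annotations)), universe)
    if (length(outside))
        message(length(outside), " annotated ligand(s) outside the model ",
                "universe are never reachable")
    sims <- simulateReachableLigands(model)
    preach <- .reachProbability(model)
    scoreSets <- function(sets) {
        vapply(sets, function(B) {
            mean(vapply(sims, function(M)
                length(intersect(M, B)) / length(B), numeric(1)))
        }, numeric(1))
    }
    meanE <- scoreSets(annotations)
    expectedE <- vapply(annotations, function(B)
        sum(preach[intersect(B, universe)]) / length(B), numeric(1))
    null95 <- rep(NA_real_, length(annotations))
    enriched <- rep(NA, length(annotations))
    if (nPerm > 0) {
        null95 <- withSeed(permSeed, {
            vapply(seq_along(annotations), function(i) {
                nB <- length(annotations[[i]])
                nullE <- vapply(seq_len(nPerm), function(b) {
                    B <- sample(universe, min(nB, length(universe)))
                    sum(preach[B]) / nB
                }, numeric(1))
                stats::quantile(nullE, 0.95, names = FALSE)
            }, numeric(1))
        })
        enriched <- meanE > null95
    }
    data.frame(process = names(annotations),
               n = lengths(annotations),
               meanE = meanE, expectedE = expectedE,
               null95 = null95, enriched = enriched,
               row.names = NULL)
}

#' Contribution of one cell type as a function of its distance
#'
#' Sweeps the reach probability of a target cell type's ligands over a
#' grid while all other probabilities stay fixed, and reports, per
#' process, the change in mean enrichment relative to the p = 0 baseline
#' (which is 0 by definition). The target's ligands are removed from
#' their home compartment and simulated as a separate compartment at each
#' grid probability; ligands the target shares with other cell types keep
#' their other routes.
#'
#' @param model a \linkS4class{CompartmentModel} (fixed probabilities)
#' @param targetLigands the ligand set of the target cell type
#' @param annotations named list: process -> ligand set
#' @param probGrid probabilities to sweep (0 is added if absent)
#' @param homeCompartment the compartment the target's exclusive ligands
#'   are removed from (default "MCN")
#' @return data.frame (process, p, deltaE)
#' @export
distanceSweep <- function(model, targetLigands, annotations,
                          probGrid = seq(0, 1, by = 0.1),
                          homeCompartment = "MCN") {
    stopifnot(is(model, "CompartmentModel"))
    if (!homeCompartment %in% model@compartments)
        stop("unknown compartment: ", homeCompartment)
    targetLigands <- toupper(targetLigands)
    probGrid <- sort(unique(c(0, probGrid)))
    rows <- list()
    baseline <- NULL
    for (i in seq_along(probGrid)) {
        p <- probGrid[i]
        sets <- model@ligandSets
        sets[[homeCompartment]] <- setdiff(sets[[homeCompartment]],
                                           targetLigands)
        sets$target <- targetLigands
        probs <- c(model@reachProb, target = p)
        m <- CompartmentModel(sets, reachProb = probs,
                              nSims = model@nSims,
                              seed = model@seed + i)
        prof <- enrichmentProfile(m, annotations, nPerm = 0L)
        if (p == 0) baseline <- prof$meanE
        rows[[i]] <- data.frame(process = prof$process, p = p,
                                deltaE = prof$meanE - baseline)
    }
    do.call(rbind, rows)
}

#' Write an enrichment profile as long-format TSV
#'
#' @param profile data.frame from \code{\link{enrichmentProfile}}
#' @param path destination path
#' @param scenario scenario label recorded per row
#' @export
writeEnrichment <- function(profile, path, scenario = "default") {
    writeTSV(cbind(scenario = scenario, profile), path)
}
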