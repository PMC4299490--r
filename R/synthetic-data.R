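#' Synthetic study design for the hematopoietic communication pipeline
#'
#' Defines the generator that stands in for the microarray and
#' flow-cytometry inputs: 12 cell types with planted, module-exclusive
#' ligand production and configurably promiscuous receptor expression, so
#' that the downstream modularity/promiscuity analyses have a known ground
#' truth. The default partition mirrors the four-module organization of the
#' hematopoietic system: a primitive module (HSCe + MLP + CMP + MEP + GMP),
#' a neutrophil-monocyte module, an erythroid module (EryB) and a module of
#' the remaining mature cells (Baso + Eos + Mega + PreB).
#'
#' @param nReplicatesPerType samples per cell type (3-10 in the emulated
#'   study; default 5)
#' @param nLigandGenes number of module-assigned ligand genes
#' @param productionModules named list partitioning cell types into
#'   production modules; ligand subsets planted per module are exclusive
#' @param bindingPromiscuity fraction in [0, 1] of ligands whose receptors
#'   jointly cover all cell types (promiscuous binding); the rest get one
#'   receptor expressed only in the producing module (specific binding)
#' @param effectSize log2-scale over-expression shift of planted genes
#' @param noiseSd log2-scale residual s.d.
#' @param nOrphanBound ligands bound by modeled cells but produced by none
#'   (routed from the "Others" node downstream)
#' @param nOrphanProduced ligands produced by modeled cells but bound by
#'   none (absorbed by "Others")
#' @param nExtraReceptors receptor genes with no interaction partner,
#'   enlarging the receptor universe for specificity estimation
#' @param housekeepingFraction fraction of the final gene matrix made of
#'   unplanted non-ligand non-receptor genes
#' @param seed integer RNG seed; fixes every generated artifact
#' @return an object of class \code{SyntheticDesign}
#' @export
syntheticDesign <- function(nReplicatesPerType = 5L,
                            nLigandGenes = 40L,
                            productionModules = list(
                                Primitive = c("HSCe", "MLP", "CMP",
                                              "MEP", "GMP"),
                                NeutMono = c("Neut", "Mono"),
                                Erythroid = "EryB",
                                OtherMature = c("Baso", "Eos", "Mega",
                                                "PreB")),
                            bindingPromiscuity = 0.8,
                            effectSize = 2,
                            noiseSd = 0.5,
                            nOrphanBound = 2L,
                            nOrphanProduced = 2L,
                            nExtraReceptors = 10L,
                            housekeepingFraction = 0.2,
                            seed = 1L) {
    cellTypes <- unlist(productionModules, use.names = FALSE)
    if (anyDuplicated(cellTypes))
        stop("production modules must partition the cell types (disjoint)")
    if (length(cellTypes) < 2L || nReplicatesPerType < 2L)
        stop("need >= 2 cell types and >= 2 replicates per type")
    if (nLigandGenes < length(productionModules))
        stop("need at least one ligand gene per production module")
    if (bindingPromiscuity < 0 || bindingPromiscuity > 1)
        stop("bindingPromiscuity must lie in [0, 1]")
    if (noiseSd <= 0) stop("noiseSd must be positive")
    if (effectSize < 0) stop("effectSize must be non-negative")
    if (housekeepingFraction < 0 || housekeepingFraction >= 1)
        stop("housekeepingFraction must lie in [0, 1)")
    structure(list(nReplicatesPerType = as.integer(nReplicatesPerType),
                   nLigandGenes = as.integer(nLigandGenes),
                   productionModules = productionModules,
                   cellTypes = cellTypes,
                   bindingPromiscuity = bindingPromiscuity,
                   effectSize = effectSize,
                   noiseSd = noiseSd,
                   nOrphanBound = as.integer(nOrphanBound),
                   nOrphanProduced = as.integer(nOrphanProduced),
                   nExtraReceptors = as.integer(nExtraReceptors),
                   housekeepingFraction = housekeepingFraction,
                   seed = as.integer(seed)),
              class = "SyntheticDesign")
}

# Deterministic wiring shared by generateExpression() and
# generateLRTable(): which ligand belongs to which production module, which
# receptors serve it, and which cell types express each receptor. Drawn
# under the design seed so both generators agree.
.syntheticArchitecture <- function(design) {
    stopifnot(inherits(design, "SyntheticDesign"))
    withSeed(design$seed, {
        mods <- design$productionModules
        nMod <- length(mods)
        ct <- design$cellTypes
        nCT <- length(ct)
        nL <- design$nLigandGenes
        lig <- sprintf("LIG%03d", seq_len(nL))
        ligModule <- names(mods)[rep_len(seq_len(nMod), nL)]
        nProm <- round(design$bindingPromiscuity * nL)
        promiscuous <- rep(FALSE, nL)
        if (nProm > 0)
            promiscuous[sample.int(nL, nProm)] <- TRUE
        recCounter <- 0L
        newRec <- function(k) {
            out <- sprintf("REC%03d", recCounter + seq_len(k))
            recCounter <<- recCounter + k
            out
        }
        pairs <- list()   # per ligand: receptor names
        recCells <- list()  # per receptor: cell types expressing it
        for (i in seq_len(nL)) {
            if (promiscuous[i]) {
                # two receptor species whose expressing cell types
                # partition the full system -> every cell binds the ligand
                rs <- newRec(2L)
                half <- sample(ct)
                k <- floor(nCT / 2)
                recCells[[rs[1]]] <- half[seq_len(k)]
                recCells[[rs[2]]] <- half[(k + 1):nCT]
            } else {
                rs <- newRec(1L)
                recCells[[rs]] <- mods[[ligModule[i]]]
            }
            pairs[[lig[i]]] <- rs
        }
        # orphan-bound: ligand gene exists but is planted nowhere; its
        # receptor is expressed -> production must come from "Others"
        orphanBound <- character(0)
        if (design$nOrphanBound > 0) {
            orphanBound <- sprintf("LIGOB%02d", seq_len(design$nOrphanBound))
            for (lg in orphanBound) {
                rs <- newRec(1L)
                recCells[[rs]] <- mods[[sample.int(nMod, 1)]]
                pairs[[lg]] <- rs
            }
        }
        # orphan-produced: ligand planted in one module but its receptor is
        # never over-expressed -> binding must go to "Others"
        orphanProduced <- character(0)
        orphanProducedModule <- character(0)
        if (design$nOrphanProduced > 0) {
            orphanProduced <- sprintf("LIGOP%02d",
                                      seq_len(design$nOrphanProduced))
            orphanProducedModule <- names(mods)[
                sample.int(nMod, design$nOrphanProduced, replace = TRUE)]
            for (lg in orphanProduced) {
                rs <- newRec(1L)
                recCells[[rs]] <- character(0)
                pairs[[lg]] <- rs
            }
        }
        extraRec <- if (design$nExtraReceptors > 0)
            sprintf("RECX%02d", seq_len(design$nExtraReceptors))
            else character(0)
        for (r in extraRec)
            recCells[[r]] <- if (stats::runif(1) < 0.5)
                mods[[sample.int(nMod, 1)]] else character(0)
        list(ligands = lig, ligModule = stats::setNames(ligModule, lig),
             promiscuous = stats::setNames(promiscuous, lig),
             pairs = pairs, recCells = recCells,
             orphanBound = orphanBound,
             orphanProduced = orphanProduced,
             orphanProducedModule = stats::setNames(orphanProducedModule,
                                                    orphanProduced),
             extraReceptors = extraRec)
    })
}

#' Generate a synthetic expression matrix with planted over-expression
#'
#' Values are normal on the log2 scale (log-normal intensities, matching
#' microarray data after normalization; the downstream test is rank-based,
#' so only the location structure matters). A gene planted as over-expressed
#' in a cell type has its mean shifted by \code{effectSize} in that type's
#' samples only. Housekeeping genes are appended so the gene universe is
#' larger than the ligand/receptor universe.
#'
#' The returned object carries the planted truth in
#' \code{S4Vectors::metadata()}: \code{$planted} is a logical gene x
#' cell-type matrix, \code{$architecture} the ligand/receptor wiring.
#'
#' @param design a \code{SyntheticDesign}
#' @return a \linkS4class{CCCExpression}
#' @export
generateExpression <- function(design) {
    stopifnot(inherits(design, "SyntheticDesign"))
    arch <- .syntheticArchitecture(design)
    ct <- design$cellTypes
    nRep <- design$nReplicatesPerType
    ligGenes <- c(arch$ligands, arch$orphanBound, arch$orphanProduced)
    recGenes <- names(arch$recCells)
    nLR <- length(ligGenes) + length(recGenes)
    nHouse <- round(design$housekeepingFraction * nLR /
                    (1 - design$housekeepingFraction))
    houseGenes <- if (nHouse > 0) sprintf("HK%03d", seq_len(nHouse))
                  else character(0)
    genes <- c(ligGenes, recGenes, houseGenes)
    role <- c(rep("ligand", length(ligGenes)),
              rep("receptor", length(recGenes)),
              rep("housekeeping", length(houseGenes)))
    # planted truth: gene x cell type
    planted <- matrix(FALSE, length(genes), length(ct),
                      dimnames = list(genes, ct))
    mods <- design$productionModules
    for (lg in arch$ligands)
        planted[lg, mods[[arch$ligModule[[lg]]]]] <- TRUE
    for (lg in arch$orphanProduced)
        planted[lg, mods[[arch$orphanProducedModule[[lg]]]]] <- TRUE
    for (r in recGenes)
        planted[r, arch$recCells[[r]]] <- TRUE
    samples <- paste0(rep(ct, each = nRep), "_r",
                      rep(seq_len(nRep), length(ct)))
    sampleCT <- rep(ct, each = nRep)
    values <- withSeed(design$seed + 1L, {
        base <- 6
        mu <- base + design$effectSize * planted[, sampleCT, drop = FALSE]
        m <- mu + matrix(stats::rnorm(length(genes) * length(samples),
                                      sd = design$noiseSd),
                         length(genes), length(samples))
        pmax(m, 0)
    })
    dimnames(values) <- list(genes, samples)
    obj <- CCCExpression(values, cellType = sampleCT, role = role)
    metadata(obj)$planted <- planted
    metadata(obj)$architecture <- arch
    metadata(obj)$design <- design
    obj
}

#' Generate the ligand-receptor interaction table matching a design
#'
#' Pairs follow the same seeded wiring as \code{\link{generateExpression}}:
#' promiscuous ligands are multi-receptor, specific ligands have one
#' module-restricted receptor, and the orphan ligands exercise the "Others"
#' node. Extra receptor genes are deliberately left without partners.
#'
#' @param design a \code{SyntheticDesign}
#' @return an \linkS4class{LRInteractionTable}
#' @export
generateLRTable <- function(design) {
    arch <- .syntheticArchitecture(design)
    lig <- rep(names(arch$pairs), lengths(arch$pairs))
    rec <- unlist(arch$pairs, use.names = FALSE)
    LRInteractionTable(ligand = lig, receptor = rec)
}

# Canonical arrow pattern (HSC-enriched, progenitor, mature) used to plant
# each functional category in the synthetic culture counts; +1 raises the
# population mean, -1 lowers it.
.categoryArrows <- list(
    neutral                  = c(0, 0, 0),
    quiescence_induction     = c(0, 0, -1),
    self_renewal_induction   = c(1, 0, 0),
    differentiation_induction = c(0, 1, 1),
    proliferation_induction  = c(1, 1, 1),
    proliferation_inhibition = c(-1, -1, -1))

#' Generate synthetic in vitro culture counts
#'
#' Emulates the 7-day liquid-culture readout: per well, counts of
#' HSC-enriched, progenitor and mature cells under a basal-control
#' condition and one condition per test ligand, across several independent
#' experiments. Counts are rounded log-normal draws with a shared
#' per-experiment random intercept (so the downstream mixed model with the
#' experiment identifier as random effect is correctly specified). The
#' basal-control means reproduce the reference culture output: about 704
#' total cells split 6.35% / 27.75% / 65.90% across the three populations.
#'
#' @param trueCategories named character vector ligand -> functional
#'   category (one of \code{names(hemaCCC:::.categoryArrows)})
#' @param nExperiments number of independent experiments (each contains the
#'   basal control)
#' @param replicates wells per condition per experiment
#' @param experimentSd s.d. of the per-experiment random intercept
#'   (log scale)
#' @param residualSd residual s.d. (log scale)
#' @param effect log-scale mean shift applied where the category's arrow
#'   pattern is non-zero
#' @param dose nominal dose recorded for ligand conditions (ng/ml)
#' @param seed RNG seed
#' @return data.frame with columns \code{experiment}, \code{condition},
#'   \code{dose}, \code{n_hsc_enriched}, \code{n_progenitor},
#'   \code{n_mature}, \code{n_total}
#' @export
generateInvitroCounts <- function(trueCategories, nExperiments = 3L,
                                  replicates = 3L, experimentSd = 0.2,
                                  residualSd = 0.25, effect = 0.5,
                                  dose = 10, seed = 1L) {
    if (is.null(names(trueCategories)) || !length(trueCategories))
        stop("trueCategories must be a named ligand -> category vector")
    bad <- setdiff(unique(trueCategories), names(.categoryArrows))
    if (length(bad))
        stop("unknown functional category: ", paste(bad, collapse = ", "))
    if (nExperiments < 2L || replicates < 1L)
        stop("need >= 2 experiments and >= 1 replicate well")
    if (experimentSd < 0 || residualSd <= 0)
        stop("experimentSd must be >= 0 and residualSd > 0")
    baseMeans <- 704 * c(0.0635, 0.2775, 0.6590)
    conditions <- c("basal_control", names(trueCategories))
    withSeed(seed, {
        rows <- list()
        for (e in seq_len(nExperiments)) {
            b <- stats::rnorm(1, 0, experimentSd)
            for (cond in conditions) {
                arrows <- if (cond == "basal_control") c(0, 0, 0)
                          else .categoryArrows[[trueCategories[[cond]]]]
                for (w in seq_len(replicates)) {
                    mu <- log(baseMeans) + b + effect * arrows
                    cnt <- round(exp(mu + stats::rnorm(3, 0, residualSd)))
                    rows[[length(rows) + 1L]] <- data.frame(
                        experiment = paste0("E", e),
                        condition = cond,
                        dose = if (cond == "basal_control") 0 else dose,
                        n_hsc_enriched = cnt[1],
                        n_progenitor = cnt[2],
                        n_mature = cnt[3],
                        n_total = sum(cnt))
                }
            }
        }
        do.call(rbind, rows)
    })
}

#' Write / read an expression matrix as TSV with a two-row header
#'
#' Row 1 holds the sample ids, row 2 the cell-type label of each sample;
#' subsequent rows are genes. An optional \code{role} column (first data
#' column) records the gene role.
#'
#' @param x a \linkS4class{CCCExpression}
#' @param path destination path
#' @return \code{path} (writer) or a \linkS4class{CCCExpression} (reader)
#' @export
writeExpressionTSV <- function(x, path) {
    stopifnot(is(x, "CCCExpression"))
    v <- SummarizedExperiment::assay(x, 1)
    rd <- SummarizedExperiment::rowData(x)
    role <- if ("role" %in% colnames(rd)) as.character(rd$role)
            else rep(NA_character_, nrow(x))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("gene", "role", colnames(v)), collapse = "\t"), con)
    writeLines(paste(c("", "cell_type",
                       as.character(x$cellType)), collapse = "\t"), con)
    utils::write.table(data.frame(gene = rownames(v), role = role, v,
                                  check.names = FALSE),
                       con, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    invisible(path)
}

#' @rdname writeExpressionTSV
#' @export
readExpressionTSV <- function(path) {
    hdr <- readLines(path, n = 2L)
    samples <- strsplit(hdr[1], "\t", fixed = TRUE)[[1]][-(1:2)]
    cellType <- strsplit(hdr[2], "\t", fixed = TRUE)[[1]][-(1:2)]
    df <- utils::read.delim(path, skip = 2L, header = FALSE,
                            stringsAsFactors = FALSE)
    genes <- df[[1]]
    role <- df[[2]]
    v <- as.matrix(df[, -(1:2), drop = FALSE])
    dimnames(v) <- list(genes, samples)
    CCCExpression(v, cellType = cellType,
                  role = if (all(is.na(role))) NULL else role)
}
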