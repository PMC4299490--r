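#' Run the full communication-network pipeline
#'
#' Orchestrates the stages in study order: (1) load or simulate the
#' expression data and interaction table, call over-expressed genes and
#' build the bipartite network; (2) analyse production-network modularity
#' and binding-network co-clustering, and compute frequency-weighted
#' competition for each scenario; (3) if culture counts are provided,
#' derive signed p-values, classify ligands, and test prediction
#' capacity. Every stage writes its outputs into \code{outDir} and a
#' provenance manifest records input hashes, parameters and seeds.
#' Re-running with an identical config reproduces identical outputs.
#'
#' @param config a named list or the path to a YAML file with fields:
#'   \code{expression} (TSV path; omit to simulate), \code{lrTable}
#'   (TSV path; omit to simulate), \code{benchmark} (optional TSV),
#'   \code{counts} (optional culture-count TSV), \code{scenarios}
#'   (optional named list of frequency TSV paths), \code{fdr} (default
#'   0.1), \code{minWins} (default 6), \code{heteromericMode} (default
#'   FALSE), \code{kRange} (default 2:6), \code{coclusterK} (default 4),
#'   \code{alpha} (default 0.02), \code{seed} (default 1), \code{outDir}
#'   (required)
#' @return invisibly, a list with the main in-memory results and the
#'   manifest path
#' @export
runPipeline <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    if (is.null(config$outDir)) stop("config field missing: outDir")
    for (fld in c("expression", "lrTable", "benchmark", "counts"))
        if (!is.null(config[[fld]]) && !file.exists(config[[fld]]))
            stop("config field '", fld, "' points to a missing file: ",
                 config[[fld]])
    cfg <- list(fdr = config$fdr %||% 0.1,
                minWins = as.integer(config$minWins %||% 6L),
                heteromericMode = isTRUE(config$heteromericMode),
                kRange = config$kRange %||% 2:6,
                coclusterK = as.integer(config$coclusterK %||% 4L),
                alpha = config$alpha %||% 0.02,
                seed = as.integer(config$seed %||% 1L))
    outDir <- config$outDir
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    inputs <- list()
    # stage 1a: inputs
    res <- stage("load-data", {
        if (is.null(config$expression)) {
            design <- syntheticDesign(seed = cfg$seed)
            dat <- generateExpression(design)
            lr <- generateLRTable(design)
            writeExpressionTSV(dat, file.path(outDir, "expression.tsv"))
            writeLRTable(lr, file.path(outDir, "lr_table.tsv"))
        } else {
            dat <- readExpressionTSV(config$expression)
            inputs$expression <- config$expression
            lr <- readLRTable(config$lrTable)
            inputs$lrTable <- config$lrTable
        }
        list(dat = dat, lr = lr, inputs = inputs)
    })
    dat <- res$dat; lr <- res$lr; inputs <- res$inputs
    # stage 1b: over-expression calls (ROC threshold if benchmarked)
    roc <- NULL
    fdrUsed <- cfg$fdr
    if (!is.null(config$benchmark)) {
        roc <- stage("roc-threshold", {
            bm <- readBenchmark(config$benchmark)
            inputs$benchmark <- config$benchmark
            selectFdrByROC(dat, lr, bm, minWins = cfg$minWins)
        })
        fdrUsed <- roc$chosen
        writeTSV(roc$table, file.path(outDir, "roc_table.tsv"))
    }
    calls <- stage("diffexpr",
        callOverexpressed(dat, lr, fdr = fdrUsed,
                          minWins = cfg$minWins))
    writeCalls(calls, file.path(outDir, "calls.tsv"))
    # stage 1c: network
    net <- stage("build-net",
        buildNetwork(calls, lr, heteromericMode = cfg$heteromericMode))
    writeNetworkMatrices(net, file.path(outDir, "network"))
    writeNetworkEdgeList(net, file.path(outDir, "network_edges.tsv"))
    writeTSV(rankCellsByDegree(net), file.path(outDir, "degrees.tsv"))
    # stage 2a: structure
    A <- productionNetwork(net, producingOnly = TRUE)
    partition <- stage("structure-production",
        clusterProduction(A, kRange = cfg$kRange))
    writeTSV(data.frame(cell = names(partition$assignment),
                        module = partition$assignment),
             file.path(outDir, "production_modules.tsv"))
    B <- bindingNetwork(net, bindingOnly = TRUE)
    B <- B[rowSums(B) > 0, , drop = FALSE]
    coclust <- stage("structure-binding",
        coclusterBinding(B, k = cfg$coclusterK, seed = cfg$seed))
    writeTSV(data.frame(node = c(names(coclust$rowAssignment),
                                 names(coclust$colAssignment)),
                        kind = c(rep("ligand",
                                     length(coclust$rowAssignment)),
                                 rep("cell",
                                     length(coclust$colAssignment))),
                        cocluster = c(coclust$rowAssignment,
                                      coclust$colAssignment)),
             file.path(outDir, "binding_coclusters.tsv"))
    # stage 2b: competition scenarios
    pac <- NULL
    if (!is.null(config$scenarios)) {
        pac <- stage("pac", {
            scen <- lapply(config$scenarios, readFrequencies)
            for (nm in names(config$scenarios))
                inputs[[paste0("scenario_", nm)]] <-
                    config$scenarios[[nm]]
            pacScenarios(net, scen)
        })
        for (nm in names(pac))
            writePAC(pac[[nm]]$pac,
                     file.path(outDir, paste0("pac_", nm, ".tsv")))
    }
    # stage 3a: in vitro ligand effects
    records <- NULL
    if (!is.null(config$counts)) {
        records <- stage("effects", {
            counts <- utils::read.delim(config$counts,
                                        stringsAsFactors = FALSE)
            inputs$counts <- config$counts
            conds <- setdiff(unique(counts$condition), "basal_control")
            do.call(rbind, lapply(conds, function(cd) {
                sp <- signedPValues(counts, cd)
                data.frame(ligand = cd,
                           p_hsc = sp[["hsc_enriched"]],
                           p_prog = sp[["progenitor"]],
                           p_mature = sp[["mature"]],
                           category = classifyLigand(sp, cfg$alpha))
            }))
        })
        writeTSV(records, file.path(outDir, "ligand_effects.tsv"))
    }
    # provenance
    manifest <- list(parameters = cfg, fdrUsed = fdrUsed,
                     inputs = lapply(inputs, function(pth)
                         list(path = pth,
                              md5 = unname(tools::md5sum(pth)))))
    manifestPath <- file.path(outDir, "manifest.json")
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    invisible(list(data = dat, lr = lr, calls = calls, net = net,
                   roc = roc, partition = partition, coclust = coclust,
                   pac = pac, records = records,
                   manifest = manifestPath))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
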