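#' Read a ligand-receptor interaction table from TSV
#'
#' Expects a tab-separated file with a header row and mandatory columns
#' \code{ligand} and \code{receptor}; optional columns \code{confidence}
#' (numeric in [0, 1], default 1) and \code{heteromericGroup} (complex
#' label shared by receptor subunits that must be co-expressed to bind).
#' Duplicate pairs are collapsed with a warning.
#'
#' @param path path to the TSV file
#' @return an \linkS4class{LRInteractionTable}
#' @export
readLRTable <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    if (nrow(df) == 0L) stop("empty interaction table: ", path)
    if (!all(c("ligand", "receptor") %in% colnames(df)))
        stop("interaction table needs 'ligand' and 'receptor' columns: ",
             path)
    LRInteractionTable(
        ligand = df$ligand, receptor = df$receptor,
        confidence = if ("confidence" %in% colnames(df)) df$confidence,
        heteromericGroup = if ("heteromericGroup" %in% colnames(df))
            df$heteromericGroup)
}

#' Write a ligand-receptor interaction table to TSV
#'
#' @param table an \linkS4class{LRInteractionTable}
#' @param path destination path
#' @return \code{path}, invisibly
#' @export
writeLRTable <- function(table, path) {
    stopifnot(is(table, "LRInteractionTable"))
    utils::write.table(as.data.frame(table@pairs), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Cognate partners of a ligand or receptor
#'
#' @param table an \linkS4class{LRInteractionTable}
#' @param ligand,receptor a single gene symbol (case-insensitive)
#' @return character vector of partner gene symbols (possibly empty)
#' @export
cognateReceptors <- function(table, ligand) {
    stopifnot(is(table, "LRInteractionTable"))
    p <- table@pairs
    unique(p$receptor[p$ligand == toupper(ligand)])
}

#' @rdname cognateReceptors
#' @export
cognateLigands <- function(table, receptor) {
    stopifnot(is(table, "LRInteractionTable"))
    p <- table@pairs
    unique(p$ligand[p$receptor == toupper(receptor)])
}

#' Read ligand-set annotations (biological processes)
#'
#' Long-format, two-column TSV with header \code{process} and \code{ligand};
#' one row per (process, member ligand).
#'
#' @param path path to the TSV file
#' @return named list: process -> character vector of member ligands
#' @export
readLigandSets <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("process", "ligand") %in% colnames(df)))
        stop("ligand-set file needs 'process' and 'ligand' columns")
    sets <- split(toupper(df$ligand), df$process)
    sets <- lapply(sets, unique)
    if (any(lengths(sets) == 0L)) stop("empty ligand set in ", path)
    sets
}

#' @rdname readLigandSets
#' @param sets named list of ligand sets
#' @export
writeLigandSets <- function(sets, path) {
    df <- data.frame(process = rep(names(sets), lengths(sets)),
                     ligand = unlist(sets, use.names = FALSE))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Rank ligands by interaction confidence
#'
#' Used to prioritize stem-cell-targeting ligands for in vitro testing. A
#' ligand's score aggregates the confidence of its pairs (default: the
#' maximum over its receptors; the aggregation rule is configurable since
#' several receptors can serve one ligand) and, optionally, is broken by the
#' summed receptor expression supplied in \code{receptorLevels}.
#'
#' @param table an \linkS4class{LRInteractionTable}
#' @param ligands ligands to rank (default: all in the table)
#' @param aggregate how to combine confidences over a ligand's receptors:
#'   \code{"max"} (default), \code{"mean"} or \code{"sum"}
#' @param receptorLevels optional named numeric of receptor expression used
#'   as a tie-break (summed over the ligand's receptors)
#' @return data.frame (ligand, score, receptorLevel) sorted best-first
#' @export
rankLigandsByConfidence <- function(table, ligands = NULL,
                                    aggregate = c("max", "mean", "sum"),
                                    receptorLevels = NULL) {
    stopifnot(is(table, "LRInteractionTable"))
    aggregate <- match.arg(aggregate)
    p <- as.data.frame(table@pairs)
    if (is.null(ligands)) ligands <- unique(p$ligand)
    ligands <- toupper(ligands)
    agg <- switch(aggregate, max = max, mean = mean, sum = sum)
    score <- vapply(ligands, function(lg) {
        cf <- p$confidence[p$ligand == lg]
        if (!length(cf)) NA_real_ else agg(cf)
    }, numeric(1))
    rlev <- vapply(ligands, function(lg) {
        if (is.null(receptorLevels)) return(0)
        rs <- p$receptor[p$ligand == lg]
        sum(receptorLevels[rs], na.rm = TRUE)
    }, numeric(1))
    out <- data.frame(ligand = ligands, score = score, receptorLevel = rlev)
    out[order(-out$score, -out$receptorLevel, out$ligand), , drop = FALSE]
}
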