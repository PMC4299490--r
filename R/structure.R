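# Pairwise Jaccard distances between the rows of a binary matrix:
# 1 - |intersection| / |union| of the produced-ligand sets. A pair of
# all-zero rows has an undefined Jaccard ratio; such pairs get distance 0
# (identical empty portfolios) with a warning.
.jaccardDist <- function(A) {
    n <- nrow(A)
    d <- matrix(0, n, n, dimnames = list(rownames(A), rownames(A)))
    warned <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        un <- sum(A[i, ] | A[j, ])
        if (un == 0) {
            warned <- TRUE
            dij <- 0
        } else dij <- 1 - sum(A[i, ] & A[j, ]) / un
        d[i, j] <- d[j, i] <- dij
    }
    if (warned)
        warning("cell pair(s) with empty ligand sets: Jaccard distance ",
                "set to 0")
    stats::as.dist(d)
}

#' Cluster the ligand production network into cell modules
#'
#' Cells are clustered on the Jaccard distance between their produced
#' ligand sets (appropriate for a binary adjacency matrix) by
#' agglomerative hierarchical clustering with Ward linkage. The dendrogram
#' is cut at every k in \code{kRange}; the partition maximizing the mean
#' silhouette width on the Jaccard distance matrix is returned. k can be
#' pinned by passing a single-value \code{kRange}.
#'
#' @param A binary cell x ligand production matrix
#' @param kRange candidate module counts (default 2:6); values outside
#'   [2, n-1] are dropped
#' @return a list of class \code{ModulePartition}: \code{assignment}
#'   (named module ids), \code{k}, \code{silhouette} (per-cell widths),
#'   \code{meanSilhouettePerK} (data.frame k/meanSilhouette),
#'   \code{hclust} (the tree)
#' @export
clusterProduction <- function(A, kRange = 2:6) {
    A <- as.matrix(A)
    if (nrow(A) < 3) stop("need at least 3 cells to cluster")
    if (!all(A %in% c(0, 1))) stop("A must be binary")
    kRange <- kRange[kRange >= 2 & kRange <= nrow(A) - 1]
    if (!length(kRange)) stop("no admissible k in kRange")
    d <- .jaccardDist(A)
    hc <- stats::hclust(d, method = "ward.D2")
    best <- NULL
    msil <- data.frame(k = kRange, meanSilhouette = NA_real_)
    for (i in seq_along(kRange)) {
        k <- kRange[i]
        cut <- stats::cutree(hc, k = k)
        sil <- cluster::silhouette(cut, d)
        msil$meanSilhouette[i] <- mean(sil[, "sil_width"])
        if (is.null(best) ||
            msil$meanSilhouette[i] > best$meanSil + 1e-12) {
            best <- list(k = k, cut = cut,
                         sil = stats::setNames(sil[, "sil_width"],
                                               rownames(A)),
                         meanSil = msil$meanSilhouette[i])
        }
    }
    structure(list(assignment = best$cut, k = best$k,
                   silhouette = best$sil,
                   meanSilhouettePerK = msil, hclust = hc),
              class = "ModulePartition")
}

#' @export
print.ModulePartition <- function(x, ...) {
    cat("ModulePartition: k =", x$k, " mean silhouette =",
        round(mean(x$silhouette), 3), "\n")
    for (m in sort(unique(x$assignment)))
        cat("  module", m, ":",
            paste(names(x$assignment)[x$assignment == m],
                  collapse = " "), "\n")
    invisible(x)
}

#' Bipartite spectral co-clustering of the ligand binding network
#'
#' Dhillon's algorithm for weighted bipartite adjacency matrices: normalize
#' \code{An = Dr^(-1/2) B Dc^(-1/2)} with the row/column degree diagonals,
#' take singular vectors 2..(ceiling(log2(k)) + 1), embed rows and columns
#' jointly (each scaled by its D^(-1/2)) and k-means the joint embedding
#' into k co-clusters under a fixed seed.
#'
#' Near-equal leading singular values signal a non-separable (promiscuous)
#' matrix; the result carries them so callers can report
#' non-separability.
#'
#' @param B non-negative ligand x cell matrix with no all-zero row/column
#' @param k number of co-clusters (>= 2)
#' @param seed k-means seed (recorded in the result)
#' @param nstart k-means restarts
#' @param nVectors number of non-trivial singular vectors to embed with
#'   (vectors 2..nVectors+1). Default k - 1: when the bipartite graph has
#'   k near-disconnected blocks the leading singular value has
#'   multiplicity k, and fewer than k - 1 vectors can project two blocks
#'   onto the same point; ceiling(log2(k)) reproduces the original
#'   prescription
#' @return a list of class \code{CoclusterResult}: \code{rowAssignment}
#'   (ligand -> co-cluster), \code{colAssignment} (cell -> co-cluster),
#'   \code{k}, \code{singularValues} (the full spectrum of An),
#'   \code{seed}
#' @export
coclusterBinding <- function(B, k, seed = 0L, nstart = 25L,
                             nVectors = k - 1L) {
    B <- as.matrix(B)
    if (k < 2) stop("k must be >= 2")
    if (any(B < 0)) stop("B must be non-negative")
    zr <- rowSums(B) == 0
    zc <- colSums(B) == 0
    if (any(zr))
        stop("all-zero row(s): ",
             paste(rownames(B)[zr], collapse = ", "))
    if (any(zc))
        stop("all-zero column(s): ",
             paste(colnames(B)[zc], collapse = ", "))
    dr <- 1 / sqrt(rowSums(B))
    dc <- 1 / sqrt(colSums(B))
    An <- B * (dr %o% dc)
    sv <- svd(An)
    take <- seq(2L, min(1L + max(1L, nVectors), min(dim(An))))
    U <- sv$u[, take, drop = FALSE] * dr
    V <- sv$v[, take, drop = FALSE] * dc
    Z <- rbind(U, V)
    km <- withSeed(seed, stats::kmeans(Z, centers = k, nstart = nstart,
                                       iter.max = 100L))
    nr <- nrow(B)
    structure(list(
        rowAssignment = stats::setNames(km$cluster[seq_len(nr)],
                                        rownames(B)),
        colAssignment = stats::setNames(km$cluster[(nr + 1):(nr + ncol(B))],
                                        colnames(B)),
        k = as.integer(k), singularValues = sv$d, seed = as.integer(seed)),
        class = "CoclusterResult")
}

#' @export
print.CoclusterResult <- function(x, ...) {
    cat("CoclusterResult: k =", x$k, "(seed", x$seed, ")\n")
    cat("  leading singular values:",
        paste(round(utils::head(x$singularValues, 5), 3), collapse = " "),
        "\n")
    cat("  cells:",
        paste(names(x$colAssignment), x$colAssignment, sep = ":",
              collapse = " "), "\n")
    invisible(x)
}

#' Compare ligand sharing between modules of two networks
#'
#' For each network, computes the number of shared ligands between every
#' pair of modules (vector S for the production / ligand-source side,
#' vector T for the binding / ligand-sink side) and runs a two-sample
#' t-test on the two vectors. A modular network shows small inter-module
#' overlaps; a promiscuous one large overlaps.
#'
#' @param ligandSetsProd named list: production module -> ligand set
#' @param ligandSetsBind named list: binding module -> ligand set
#' @param variant \code{"welch"} (default) or \code{"pooled"} t-test
#' @return list: \code{S}, \code{T} (pairwise overlap counts),
#'   \code{t}, \code{p}, \code{variant}
#' @export
compareModuleOverlap <- function(ligandSetsProd, ligandSetsBind,
                                 variant = c("welch", "pooled")) {
    variant <- match.arg(variant)
    pairOverlaps <- function(sets) {
        if (length(sets) < 2)
            stop("need >= 2 modules to form inter-module pairs")
        n <- length(sets)
        out <- numeric(0)
        for (i in seq_len(n - 1)) for (j in (i + 1):n)
            out <- c(out, length(intersect(sets[[i]], sets[[j]])))
        out
    }
    S <- pairOverlaps(ligandSetsProd)
    T_ <- pairOverlaps(ligandSetsBind)
    tt <- .overlapT(S, T_, variant)
    list(S = S, T = T_, t = tt$t, p = tt$p, variant = variant)
}

#' Two-sample t-test on precomputed overlap vectors
#'
#' Convenience wrapper for comparing overlap vectors that were derived
#' elsewhere (e.g. printed module-overlap counts).
#'
#' @param S,T numeric overlap vectors for the two networks
#' @param variant \code{"welch"} (default) or \code{"pooled"}
#' @return list with \code{t}, \code{p}, \code{variant}
#' @export
overlapTTest <- function(S, T, variant = c("welch", "pooled")) {
    variant <- match.arg(variant)
    tt <- .overlapT(S, T, variant)
    list(t = tt$t, p = tt$p, variant = variant)
}

# t.test wrapper tolerating the degenerate constant case (identical
# overlap patterns compare as t = 0, p = 1).
.overlapT <- function(S, T_, variant) {
    if (stats::sd(c(S, T_)) == 0)
        return(list(t = 0, p = 1))
    tt <- stats::t.test(S, T_, var.equal = (variant == "pooled"))
    list(t = unname(tt$statistic), p = tt$p.value)
}

#' Module ligand sets from a partition and a production matrix
#'
#' @param A binary cell x ligand matrix
#' @param assignment named cell -> module id vector
#' @return named list module -> union of ligands produced by its cells
#' @export
moduleLigandSets <- function(A, assignment) {
    A <- as.matrix(A)
    mods <- sort(unique(assignment))
    out <- lapply(mods, function(m) {
        cells <- names(assignment)[assignment == m]
        colnames(A)[colSums(A[cells, , drop = FALSE]) > 0]
    })
    names(out) <- paste0("module", mods)
    out
}

#' Bootstrap confidence of production-network cell clusters
#'
#' Resamples ligand columns with replacement, re-clusters, and reports per
#' original module the fraction of bootstrap replicates in which its cell
#' set is recovered exactly as a cluster. An ordinary bootstrap: it scores
#' stability of the module composition, not a calibrated p-value.
#'
#' @param A binary cell x ligand matrix
#' @param partition a \code{ModulePartition} from
#'   \code{\link{clusterProduction}}
#' @param nBoot bootstrap replicates (default 100)
#' @param seed RNG seed
#' @return named numeric: per-module recovery fraction in [0, 1]
#' @export
bootstrapClusterConfidence <- function(A, partition, nBoot = 100L,
                                       seed = 1L) {
    A <- as.matrix(A)
    stopifnot(inherits(partition, "ModulePartition"))
    mods <- split(names(partition$assignment), partition$assignment)
    hits <- stats::setNames(numeric(length(mods)),
                            paste0("module", names(mods)))
    withSeed(seed, {
        for (b in seq_len(nBoot)) {
            Ab <- A[, sample.int(ncol(A), replace = TRUE), drop = FALSE]
            d <- suppressWarnings(.jaccardDist(Ab))
            hc <- stats::hclust(d, method = "ward.D2")
            cut <- stats::cutree(hc, k = partition$k)
            groups <- split(names(cut), cut)
            for (i in seq_along(mods)) {
                found <- any(vapply(groups, function(g)
                    setequal(g, mods[[i]]), logical(1)))
                if (found) hits[i] <- hits[i] + 1
            }
        }
    })
    hits / nBoot
}
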