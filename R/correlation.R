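## Cross-tissue correlation structure of a gene set, hierarchical
## clustering of tissues, a gene-set permutation test for a low-correlation
## tissue group, and per-gene-family correlation profiles.

logFPKM <- function(v) log10(v + 1)

#' Pairwise cross-tissue Pearson correlation over a gene set
#'
#' Correlates each pair of tissues using the expression profile of the
#' selected genes, by default on the log10(FPKM + 1) scale (raw FPKM via
#' `logTransform = FALSE`). Tissue pairs where either tissue has zero
#' variance across the gene set yield `NA` with a message.
#'
#' @param m a [FPKMExperiment-class].
#' @param geneSet character vector of genes (>= 2 must be present in `m`).
#' @param logTransform correlate log10(FPKM + 1) profiles (default `TRUE`).
#' @param geneSetId label stored on the result.
#' @return A symmetric correlation matrix (tissues x tissues, diagonal 1)
#'   with attributes `geneSetId` and `nGenes`.
#' @export
crossTissueCorrelation <- function(m, geneSet = NULL, logTransform = TRUE,
                                   geneSetId = "geneset") {
    stopifnot(is(m, "FPKMExperiment"))
    v <- fpkm(m)
    if (!is.null(geneSet))
        v <- v[rownames(v) %in% geneSet, , drop = FALSE]
    if (nrow(v) < 2L)
        stop("need at least 2 genes from the set present in the matrix")
    if (ncol(v) < 2L)
        stop("need at least 2 tissues")
    if (logTransform)
        v <- logFPKM(v)
    sds <- apply(v, 2L, stats::sd)
    rho <- suppressWarnings(stats::cor(v, method = "pearson"))
    if (any(sds == 0)) {
        message("zero-variance tissue profile(s): ",
                paste(colnames(v)[sds == 0], collapse = ", "))
        rho[sds == 0, ] <- NA_real_
        rho[, sds == 0] <- NA_real_
    }
    diag(rho) <- 1
    attr(rho, "geneSetId") <- geneSetId
    attr(rho, "nGenes") <- nrow(v)
    rho
}

#' Hierarchically cluster tissues from a correlation matrix
#'
#' Agglomerative clustering with distance `1 - rho` and average linkage.
#' Returns the tree, the leaf order, the flat 2-group split used for the
#' low-correlation tissue analysis, and the dendrogram as Newick text.
#'
#' @param rho a complete correlation matrix as produced by
#'   [crossTissueCorrelation()].
#' @param k number of flat groups to cut (default 2).
#' @return A list with `hclust`, `leafOrder`, `groups` (named integer
#'   membership), `newick` and `degenerate` (TRUE when all off-diagonal
#'   correlations are equal, making any split arbitrary).
#' @export
clusterTissues <- function(rho, k = 2L) {
    if (anyNA(rho))
        stop("correlation matrix has missing entries; impute (e.g. by the ",
             "minimum observed correlation) or change the gene set")
    d <- stats::as.dist(1 - rho)
    hc <- stats::hclust(d, method = "average")
    off <- d[seq_along(d)]
    degenerate <- isTRUE(all(abs(off - off[1L]) < 1e-12))
    if (degenerate)
        warning("all tissue pairs equally correlated; flat split is arbitrary")
    groups <- stats::cutree(hc, k = k)
    list(hclust = hc,
         leafOrder = hc$labels[hc$order],
         groups = groups,
         newick = ape::write.tree(ape::as.phylo(hc)),
         degenerate = degenerate)
}

#' Permutation test for a low-correlation tissue group
#'
#' Statistic: the median Pearson correlation over all (in-group,
#' out-of-group) tissue pairs, computed on the gene set of interest. The
#' null is built by redrawing gene sets of equal size uniformly from all
#' genes of the matrix `nPerm` times; the one-sided p-value (is the group's
#' cross-correlation unusually \emph{low}?) uses the add-one rule
#' `p = (1 + #[null <= observed]) / (1 + nPerm)` and therefore never
#' reaches 0.
#'
#' @param m a [FPKMExperiment-class].
#' @param geneSet genes whose profile defines the statistic.
#' @param group character vector of tissues; must be a proper nonempty
#'   subset of the matrix tissues.
#' @param nPerm number of null draws (default 999; < 100 warns).
#' @param seed integer seed for the resampling stream.
#' @param logTransform see [crossTissueCorrelation()].
#' @return A list with `medianRho`, `p`, `nPerm` and the `null` vector of
#'   permuted statistics.
#' @export
lowGroupPermutationTest <- function(m, geneSet, group, nPerm = 999L,
                                    seed = 1L, logTransform = TRUE) {
    stopifnot(is(m, "FPKMExperiment"))
    tset <- tissues(m)
    group <- intersect(group, tset)
    if (length(group) == 0L)
        stop("group has no tissues in common with the matrix")
    if (length(group) == length(tset))
        stop("group must be a proper subset of the tissues")
    if (nPerm < 100L)
        warning("nPerm < 100 gives a coarse p-value resolution")
    v <- fpkm(m)
    if (logTransform) v <- logFPKM(v)
    inIdx <- which(tset %in% group)
    outIdx <- which(!tset %in% group)
    present <- intersect(geneSet, rownames(v))
    if (length(present) < 2L)
        stop("need at least 2 genes from the set present in the matrix")

    medianCross <- function(rows) {
        rho <- suppressWarnings(stats::cor(v[rows, , drop = FALSE]))
        stats::median(rho[inIdx, outIdx], na.rm = TRUE)
    }
    observed <- medianCross(present)
    nGenes <- length(present)
    allGenes <- rownames(v)
    null <- withr::with_seed(seed, vapply(seq_len(nPerm), function(i)
        medianCross(sample(allGenes, nGenes)), 0))
    p <- (1 + sum(null <= observed)) / (1 + nPerm)
    list(medianRho = observed, p = p, nPerm = nPerm, null = null)
}

#' Per-gene-family cross-tissue correlation profiles
#'
#' For each family of size >= 3, the Pearson correlation between two
#' tissues over the family members' log10(FPKM + 1) values, either for
#' every tissue pair or between one reference tissue and all others.
#' Smaller families are skipped with a message (with n = 2 members Pearson
#' is always +/-1).
#'
#' @param m a [FPKMExperiment-class].
#' @param ann a [PathwayAnnotation-class] defining the families.
#' @param referenceTissue optional tissue name; when given, only pairs
#'   (reference, other) are reported.
#' @param minFamilySize minimum family size (default 3).
#' @return `data.frame` with columns `family`, `tissue1`, `tissue2`, `rho`,
#'   `n_members`.
#' @export
familyCorrelationProfiles <- function(m, ann, referenceTissue = NULL,
                                      minFamilySize = 3L) {
    stopifnot(is(m, "FPKMExperiment"), is(ann, "PathwayAnnotation"))
    v <- logFPKM(fpkm(m))
    tset <- colnames(v)
    if (!is.null(referenceTissue) && !referenceTissue %in% tset)
        stop("reference tissue '", referenceTissue, "' not in the matrix")
    fams <- geneFamilies(ann)
    out <- list()
    for (fam in names(fams)) {
        members <- intersect(fams[[fam]], rownames(v))
        if (length(members) < minFamilySize) {
            message("skipping family '", fam, "' (", length(members),
                    " usable members)")
            next
        }
        sub <- v[members, , drop = FALSE]
        rho <- suppressWarnings(stats::cor(sub))
        pairs <- if (is.null(referenceTissue)) {
            idx <- which(upper.tri(rho), arr.ind = TRUE)
            data.frame(t1 = tset[idx[, 1L]], t2 = tset[idx[, 2L]])
        } else {
            others <- setdiff(tset, referenceTissue)
            data.frame(t1 = referenceTissue, t2 = others)
        }
        out[[fam]] <- data.frame(
            family = fam, tissue1 = pairs$t1, tissue2 = pairs$t2,
            rho = rho[cbind(pairs$t1, pairs$t2)],
            n_members = length(members), stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(family = character(0L), tissue1 = character(0L),
                          tissue2 = character(0L), rho = numeric(0L),
                          n_members = integer(0L)))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
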