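## Six HPA-style tissue-specificity categories. Detection threshold:
## a gene is "detected" in a tissue iff FPKM > 1; "not detected" everywhere
## iff FPKM < 1 in all tissues. Fold thresholds are inclusive (>= 5).

CATEGORY_LEVELS <- c("NotDetected", "TissueEnriched", "GroupEnriched",
                     "TissueEnhanced", "ExpressedInAll", "Mixed")

#' Classify one gene's cross-tissue FPKM profile
#'
#' Assigns exactly one of six categories, evaluated specificity-first so the
#' enrichment categories dominate:
#' \enumerate{
#'   \item \strong{NotDetected} — FPKM < 1 in all tissues;
#'   \item \strong{TissueEnriched} — a unique top tissue with at least
#'     5-fold higher FPKM than every other tissue (ties for the top fall
#'     through);
#'   \item \strong{GroupEnriched} — a group of 2–7 tissues whose mean FPKM
#'     is at least 5-fold the maximum of all remaining tissues; groups are
#'     searched greedily as prefixes of the tissues sorted by descending
#'     FPKM, smallest qualifying prefix wins;
#'   \item \strong{TissueEnhanced} — top tissue at least 5-fold above the
#'     mean FPKM of \emph{all} tissues (itself included);
#'   \item \strong{ExpressedInAll} — FPKM > 1 in every tissue;
#'   \item \strong{Mixed} — everything else (detected in some but not
#'     matching any rule above).
#' }
#' All fold comparisons are inclusive (>= 5).
#'
#' @param x named numeric vector of FPKM values over tissues (length >= 2,
#'   nonnegative, no NA/NaN).
#' @param foldThreshold enrichment fold threshold (default 5).
#' @param detectionThreshold FPKM detection cutoff (default 1).
#' @return A list with `category`, `witness_tissue` (comma-joined for a
#'   group; `NA` when no witness applies) and `witness_fold` (`NA` likewise;
#'   `Inf` when the comparison set is all zero).
#' @examples
#' classifyGene(c(liver = 50, lung = 10, heart = 3))
#' @export
classifyGene <- function(x, foldThreshold = 5, detectionThreshold = 1) {
    x <- unlist(x)
    if (length(x) < 2L)
        stop("need FPKM values for at least 2 tissues")
    if (anyNA(x) || any(is.nan(x)))
        stop("FPKM vector contains NA/NaN")
    if (any(x < 0))
        stop("FPKM values must be nonnegative")
    if (is.null(names(x)))
        names(x) <- paste0("tissue", seq_along(x))
    n <- length(x)

    noWitness <- function(cat)
        list(category = cat, witness_tissue = NA_character_,
             witness_fold = NA_real_)

    ## (1) NotDetected
    if (all(x < detectionThreshold))
        return(noWitness("NotDetected"))

    ord <- order(-x, names(x))
    xs <- x[ord]

    ## (2) TissueEnriched: unique top tissue, >= fold x every other tissue
    if (xs[1L] > xs[2L]) {
        fold <- if (xs[2L] > 0) xs[1L] / xs[2L] else Inf
        if (fold >= foldThreshold)
            return(list(category = "TissueEnriched",
                        witness_tissue = names(xs)[1L],
                        witness_fold = unname(fold)))
    }

    ## (3) GroupEnriched: greedy prefix groups of size 2..7
    for (k in 2:min(7L, n - 1L)) {
        rest <- xs[(k + 1L):n]
        grpMean <- mean(xs[seq_len(k)])
        fold <- if (max(rest) > 0) grpMean / max(rest) else Inf
        if (fold >= foldThreshold)
            return(list(category = "GroupEnriched",
                        witness_tissue = paste(names(xs)[seq_len(k)],
                                               collapse = ","),
                        witness_fold = unname(fold)))
    }

    ## (5) TissueEnhanced: top tissue >= fold x mean of all tissues
    if (mean(x) > 0 && xs[1L] / mean(x) >= foldThreshold)
        return(list(category = "TissueEnhanced",
                    witness_tissue = names(xs)[1L],
                    witness_fold = unname(xs[1L] / mean(x))))

    ## (4) ExpressedInAll: detected (FPKM > threshold) in every tissue
    if (all(x > detectionThreshold))
        return(noWitness("ExpressedInAll"))

    ## (6) Mixed
    noWitness("Mixed")
}

#' Classify every gene of an FPKM matrix
#'
#' @param m a [FPKMExperiment-class].
#' @param geneSet optional character vector restricting the calls (e.g. the
#'   pathway genes); genes absent from the matrix are ignored.
#' @param foldThreshold,detectionThreshold see [classifyGene()].
#' @return `data.frame` with columns `gene`, `category` (factor over the six
#'   levels), `witness_tissue`, `witness_fold`; the per-category counts are
#'   available via [categoryCounts()].
#' @export
classifyAll <- function(m, geneSet = NULL, foldThreshold = 5,
                        detectionThreshold = 1) {
    stopifnot(is(m, "FPKMExperiment"))
    v <- fpkm(m)
    if (!is.null(geneSet))
        v <- v[rownames(v) %in% geneSet, , drop = FALSE]
    if (nrow(v) == 0L)
        stop("no genes to classify")
    calls <- lapply(seq_len(nrow(v)), function(i)
        classifyGene(v[i, ], foldThreshold, detectionThreshold))
    data.frame(
        gene = rownames(v),
        category = factor(vapply(calls, `[[`, "", "category"),
                          levels = CATEGORY_LEVELS),
        witness_tissue = vapply(calls, `[[`, "", "witness_tissue"),
        witness_fold = vapply(calls, `[[`, 0, "witness_fold"),
        stringsAsFactors = FALSE)
}

#' Per-category call counts
#'
#' @param calls output of [classifyAll()].
#' @param geneSet optional restriction to a gene set before counting.
#' @return Named integer vector over the six categories (zeros kept).
#' @export
categoryCounts <- function(calls, geneSet = NULL) {
    if (!is.null(geneSet))
        calls <- calls[calls$gene %in% geneSet, , drop = FALSE]
    table(factor(calls$category, levels = CATEGORY_LEVELS))
}

#' Write category calls as TSV
#'
#' @param calls output of [classifyAll()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeCategoryCalls <- function(calls, path) {
    utils::write.table(calls, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}
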