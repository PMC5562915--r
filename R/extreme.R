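## Family-level extreme-gene detection: each gene's share of its family's
## total FPKM is profiled across tissues and screened with the Grubbs
## statistic; above-mean outliers at p < alpha become (gene, tissue) calls,
## cross-validated against an independent expression resource.

emptyExtremeCalls <- function() {
    data.frame(gene = character(0L), family = character(0L),
               subsystem = character(0L), tissue = character(0L),
               G = numeric(0L), p = numeric(0L), fold_change = numeric(0L),
               dataset = character(0L), validated = logical(0L),
               stringsAsFactors = FALSE)
}

#' Family-share matrix
#'
#' Within a gene family, each member's share of the family's total FPKM per
#' tissue: `s[g, t] = fpkm[g, t] / sum(fpkm[family, t])`. Shares remove
#' tissue-level library-size scaling and the family-total variation across
#' tissues. Tissues with zero family total get missing shares (message).
#'
#' @param m a [FPKMExperiment-class].
#' @param family character vector of member genes (>= 3 present in `m`).
#' @return Matrix of shares (members x tissues); columns sum to 1 where the
#'   family total is positive, `NA` otherwise.
#' @export
familyShare <- function(m, family) {
    stopifnot(is(m, "FPKMExperiment"))
    v <- fpkm(m)[intersect(family, rownames(m)), , drop = FALSE]
    if (nrow(v) < 3L)
        stop("need at least 3 family members present in the matrix")
    tot <- colSums(v)
    if (any(tot == 0))
        message("zero family total in tissue(s): ",
                paste(colnames(v)[tot == 0], collapse = ", "))
    sweep(v, 2L, ifelse(tot > 0, tot, NA_real_), "/")
}

#' Detect tissue-specific extreme genes per gene family
#'
#' For each gene of each annotated family (size >= `minFamilySize` after
#' intersection with the matrix), the Grubbs statistic is computed on the
#' gene's cross-tissue profile — by default its family-share vector — and a
#' call `(gene, argmax tissue)` is emitted when the two-sided p-value is
#' below `alpha` and the outlying tissue lies \emph{above} the mean
#' (expression spikes). Below-mean outliers passing `alpha` are reported
#' separately in the `"belowMean"` attribute. With `iterate = TRUE` the
#' called tissue is masked and the gene re-tested up to `maxDepth` calls.
#' The fold change is computed on raw FPKM: the gene's FPKM in the called
#' tissue over its median FPKM across the other tissues.
#'
#' @param m a [FPKMExperiment-class].
#' @param ann a [PathwayAnnotation-class] whose families define the test
#'   units.
#' @param alpha call threshold on the (optionally BH-adjusted) p-value.
#' @param input profile tested: `"share"` (family share, default), `"fpkm"`
#'   (raw) or `"logfpkm"` (log10(FPKM + 1)).
#' @param iterate mask-and-retest for multiple extreme tissues per gene.
#' @param maxDepth maximum calls per gene when iterating (default 2).
#' @param bhCorrect apply Benjamini-Hochberg across all first-pass gene
#'   tests before thresholding (off by default: raw p < alpha).
#' @param minFamilySize smallest usable family (default 3; degenerate or
#'   smaller families are skipped with a message).
#' @return `data.frame` of calls with columns `gene`, `family`,
#'   `subsystem`, `tissue`, `G`, `p`, `fold_change`, `dataset`,
#'   `validated` (`NA` until [consensusCalls()]); attribute `"belowMean"`
#'   holds the below-mean outliers in the same shape.
#' @export
detectExtremeGenes <- function(m, ann, alpha = 0.05,
                               input = c("share", "fpkm", "logfpkm"),
                               iterate = FALSE, maxDepth = 2L,
                               bhCorrect = FALSE, minFamilySize = 3L) {
    stopifnot(is(m, "FPKMExperiment"), is(ann, "PathwayAnnotation"))
    input <- match.arg(input)
    tab <- annotationTable(ann)
    fams <- geneFamilies(ann)
    tset <- tissues(m)
    v <- fpkm(m)

    rows <- list()
    for (fam in names(fams)) {
        members <- intersect(fams[[fam]], rownames(v))
        if (length(members) < minFamilySize) {
            message("skipping family '", fam, "' (", length(members),
                    " usable members)")
            next
        }
        prof <- switch(input,
                       share = tryCatch(familyShare(m, members),
                                        error = function(e) NULL),
                       fpkm = v[members, , drop = FALSE],
                       logfpkm = logFPKM(v[members, , drop = FALSE]))
        if (is.null(prof))
            next
        for (g in members) {
            x <- prof[g, ]
            keep <- which(!is.na(x))
            depth <- 0L
            repeat {
                if (length(keep) < 3L) break
                res <- tryCatch(grubbsStatistic(x[keep]),
                                error = function(e) NULL)
                if (is.null(res)) {
                    message("degenerate profile for gene '", g,
                            "' in family '", fam, "'; skipped")
                    break
                }
                tIdx <- keep[res@argmax]
                raw <- v[g, ]
                fc <- raw[tIdx] / stats::median(raw[-tIdx])
                rows[[length(rows) + 1L]] <- data.frame(
                    gene = g, family = fam,
                    subsystem = tab$subsystem[match(g, tab$gene)],
                    tissue = tset[tIdx], G = res@G,
                    p = grubbsPvalue(res@G, res@n),
                    fold_change = unname(fc),
                    dataset = datasetId(m),
                    direction = res@direction,
                    pass = depth + 1L,
                    stringsAsFactors = FALSE)
                depth <- depth + 1L
                if (!iterate || depth >= maxDepth) break
                if (rows[[length(rows)]]$p >= alpha) break
                keep <- setdiff(keep, tIdx)
            }
        }
    }
    if (!length(rows)) {
        out <- emptyExtremeCalls()
        attr(out, "belowMean") <- emptyExtremeCalls()
        return(out)
    }
    all <- do.call(rbind, rows)
    if (bhCorrect) {
        first <- all$pass == 1L
        all$p[first] <- stats::p.adjust(all$p[first], method = "BH")
    }
    sig <- all[all$p < alpha, , drop = FALSE]
    keepCols <- c("gene", "family", "subsystem", "tissue", "G", "p",
                  "fold_change", "dataset")
    out <- sig[sig$direction == "above", keepCols, drop = FALSE]
    out$validated <- rep(NA, nrow(out))
    below <- sig[sig$direction == "below", keepCols, drop = FALSE]
    below$validated <- rep(NA, nrow(below))
    rownames(out) <- rownames(below) <- NULL
    attr(out, "belowMean") <- below
    out
}

#' Cross-dataset consensus of extreme calls
#'
#' A call is \emph{validated} iff the same (gene, tissue) pair was called
#' in both datasets. Tissue names are harmonized by exact case-insensitive
#' match plus an optional alias map; datasets whose tissue vocabularies are
#' disjoint raise an error suggesting an alias map. Unvalidated calls are
#' retained, flagged `validated = FALSE`.
#'
#' @param callsPrimary,callsValidation call tables from
#'   [detectExtremeGenes()] run on the two expression resources (same
#'   annotation).
#' @param aliasMap optional named character vector mapping validation
#'   dataset tissue names to primary names.
#' @return The primary call table with the `validated` column filled.
#' @export
consensusCalls <- function(callsPrimary, callsValidation, aliasMap = NULL) {
    canon <- function(tissue) {
        tissue <- as.character(tissue)
        if (!is.null(aliasMap)) {
            hit <- match(tolower(tissue), tolower(names(aliasMap)))
            tissue[!is.na(hit)] <- aliasMap[hit[!is.na(hit)]]
        }
        tolower(tissue)
    }
    if (nrow(callsPrimary) && nrow(callsValidation)) {
        if (!length(intersect(canon(callsPrimary$tissue),
                              canon(callsValidation$tissue))) &&
            !length(intersect(tolower(callsPrimary$tissue),
                              tolower(callsValidation$tissue))))
            stop("tissue vocabularies are disjoint between datasets; ",
                 "supply an alias map")
    }
    keyP <- paste(callsPrimary$gene, canon(callsPrimary$tissue), sep = "\r")
    keyV <- paste(callsValidation$gene, canon(callsValidation$tissue),
                  sep = "\r")
    callsPrimary$validated <- keyP %in% keyV
    callsPrimary
}

#' Build the bipartite tissue-gene network from extreme calls
#'
#' Gene nodes are annotated with family and subsystem; a gene called in
#' several tissues has degree > 1 (a "shared" extreme gene).
#'
#' @param calls a call table (typically the `validated == TRUE` subset of
#'   [consensusCalls()] output). An empty table yields an empty network
#'   with a warning.
#' @param ann a [PathwayAnnotation-class] (fills family/subsystem for genes
#'   missing them).
#' @return A [TissueGeneNetwork-class].
#' @export
buildNetwork <- function(calls, ann = NULL) {
    if (nrow(calls) == 0L) {
        warning("no extreme calls; building an empty network")
        return(new("TissueGeneNetwork",
                   edgeTable = emptyExtremeCalls()[
                       , c("gene", "tissue", "G", "p", "fold_change",
                           "validated")],
                   geneInfo = data.frame(gene = character(0L),
                                         family = character(0L),
                                         subsystem = character(0L))))
    }
    ed <- calls[, c("gene", "tissue", "G", "p", "fold_change", "validated")]
    ed$validated[is.na(ed$validated)] <- FALSE
    gi <- unique(calls[, c("gene", "family", "subsystem")])
    if (!is.null(ann)) {
        tab <- annotationTable(ann)
        i <- match(gi$gene, tab$gene)
        gi$family <- ifelse(is.na(gi$family), tab$family[i], gi$family)
        gi$subsystem <- ifelse(is.na(gi$subsystem), tab$subsystem[i],
                               gi$subsystem)
    }
    rownames(ed) <- rownames(gi) <- NULL
    new("TissueGeneNetwork", edgeTable = ed, geneInfo = gi)
}

#' Frequency of extreme genes per subsystem and tissue
#'
#' Aggregation behind the subsystem x tissue frequency panel of the
#' tissue-gene network figure.
#'
#' @param net a [TissueGeneNetwork-class].
#' @return Integer table (subsystem x tissue).
#' @export
subsystemTissueCounts <- function(net) {
    ed <- edges(net)
    gi <- net@geneInfo
    subsys <- gi$subsystem[match(ed$gene, gi$gene)]
    table(subsystem = subsys, tissue = ed$tissue)
}

#' Write extreme calls as TSV
#'
#' @param calls a call table.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeExtremeCalls <- function(calls, path) {
    utils::write.table(calls, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}
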