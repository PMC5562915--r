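## Tissue secretome definition, the disulfide enrichment estimator
## DS_e = log10( sum_i fpkm_i * ds_i ), and the regression linking
## processing-enzyme family expression to the per-tissue load.

#' Define the secretome analysis set
#'
#' Conventional secretome members carry a signal peptide and form the
#' analysis set. Proteins without a signal peptide but with an
#' unconventional-secretion score > `unconventionalCutoff` are excluded;
#' proteins matching neither filter are dropped. Optionally the analysis
#' set is restricted to genes in tissue-specific expression categories.
#'
#' @param ptm a [PTMTable-class].
#' @param categories optional [classifyAll()] call table used to restrict
#'   the analysis set.
#' @param restrictTo categories kept when `categories` is given (default
#'   the tissue-specific trio TissueEnriched / GroupEnriched /
#'   TissueEnhanced).
#' @param unconventionalCutoff SecretomeP-style score threshold (default
#'   0.6).
#' @return A [SecretomeSet-class]; errors when the analysis set is empty.
#' @export
defineSecretome <- function(ptm, categories = NULL,
                            restrictTo = c("TissueEnriched", "GroupEnriched",
                                           "TissueEnhanced"),
                            unconventionalCutoff = 0.6) {
    stopifnot(is(ptm, "PTMTable"))
    tab <- annotationTable(ptm)
    conventional <- tab$protein[tab$has_signal_peptide]
    noSP <- tab[!tab$has_signal_peptide, , drop = FALSE]
    excluded <- noSP$protein[!is.na(noSP$secretomep_score) &
                             noSP$secretomep_score > unconventionalCutoff]
    dropped <- setdiff(noSP$protein, excluded)
    analysis <- conventional
    if (!is.null(categories)) {
        keep <- categories$gene[categories$category %in% restrictTo]
        analysis <- intersect(analysis, keep)
    }
    if (length(analysis) == 0L)
        stop("secretome analysis set is empty")
    loc <- tab$localization[match(analysis, tab$protein)]
    names(loc) <- analysis
    loc[is.na(loc)] <- "unknown"
    new("SecretomeSet", genes = analysis, excluded = excluded,
        dropped = dropped, localization = loc)
}

#' Disulfide enrichment estimator per tissue
#'
#' For each tissue `t`, `DS_e(t) = log10( sum_i fpkm[i, t] * ds[i] )` over
#' the secretome analysis genes present in the matrix, where `ds[i]` is
#' the protein's disulfide-bond count. Genes of the analysis set missing
#' from the PTM table contribute `ds = 0` and are counted in the
#' `"nUnannotated"` attribute (flagged, not dropped). Tissues whose sum is
#' zero get `undefined = TRUE` and `ds_e = NA`; they are excluded from
#' downstream regressions.
#'
#' @param m a [FPKMExperiment-class].
#' @param sec a [SecretomeSet-class].
#' @param ptm the [PTMTable-class] supplying disulfide counts.
#' @return `data.frame` with columns `tissue`, `ds_e`, `n_genes` (genes
#'   contributing, i.e. fpkm * ds > 0) and `undefined`.
#' @examples
#' # one gene, FPKM 10, 10 disulfide bonds -> DS_e = log10(100) = 2
#' @export
disulfideEnrichment <- function(m, sec, ptm) {
    stopifnot(is(m, "FPKMExperiment"), is(sec, "SecretomeSet"),
              is(ptm, "PTMTable"))
    genes <- intersect(genes(sec), rownames(m))
    if (length(genes) == 0L)
        stop("no secretome genes present in the expression matrix")
    tab <- annotationTable(ptm)
    ds <- tab$disulfide_sites[match(genes, tab$protein)]
    nUnannotated <- sum(is.na(ds))
    if (nUnannotated > 0L)
        message(nUnannotated,
                " secretome gene(s) without PTM annotation; ds = 0")
    ds[is.na(ds)] <- 0L
    v <- fpkm(m)[genes, , drop = FALSE]
    load <- colSums(v * ds)
    out <- data.frame(
        tissue = colnames(v),
        ds_e = ifelse(load > 0, log10(load), NA_real_),
        n_genes = as.integer(colSums((v * ds) > 0)),
        undefined = load == 0,
        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "nUnannotated") <- nUnannotated
    out
}

#' Regress enzyme-family expression on the tissue disulfide load
#'
#' For each gene of a processing-enzyme family (e.g. the protein disulfide
#' isomerases), ordinary least squares of the gene's FPKM on `DS_e` across
#' tissues with defined loads, plus the Pearson correlation and its
#' two-sided t-test p-value and the 95% confidence interval of the slope.
#'
#' @param m a [FPKMExperiment-class].
#' @param family character vector of enzyme genes.
#' @param loads output of [disulfideEnrichment()].
#' @return `data.frame` with one row per gene: `gene`, `slope`,
#'   `intercept`, `slope_ci_lo`, `slope_ci_hi`, `pearson_r`, `p_value`,
#'   `n_tissues`.
#' @export
associateFamilyWithLoad <- function(m, family, loads) {
    stopifnot(is(m, "FPKMExperiment"))
    ok <- loads[!loads$undefined & !is.na(loads$ds_e), , drop = FALSE]
    if (nrow(ok) < 3L)
        stop("need at least 3 tissues with defined DS_e")
    if (stats::sd(ok$ds_e) == 0)
        stop("degenerate regression: DS_e constant across tissues")
    genes <- intersect(family, rownames(m))
    if (length(genes) == 0L)
        stop("no family genes present in the matrix")
    v <- fpkm(m)[genes, ok$tissue, drop = FALSE]
    res <- lapply(genes, function(g) {
        y <- v[g, ]
        fit <- stats::lm(y ~ ok$ds_e)
        ci <- stats::confint(fit)[2L, ]
        ct <- suppressWarnings(stats::cor.test(y, ok$ds_e))
        data.frame(gene = g,
                   slope = unname(stats::coef(fit)[2L]),
                   intercept = unname(stats::coef(fit)[1L]),
                   slope_ci_lo = unname(ci[1L]),
                   slope_ci_hi = unname(ci[2L]),
                   pearson_r = unname(ct$estimate),
                   p_value = ct$p.value,
                   n_tissues = nrow(ok),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Discretized per-gene PTM profile table
#'
#' Site counts (N-glyc, O-glyc, disulfide, GPI) per secretome gene plus a
#' low/medium/high bin per PTM type: terciles of the \emph{nonzero} counts
#' of that column, with a separate `"none"` bin for zeros. Feeds the
#' annotation bars of a clustered secretome heatmap.
#'
#' @param sec a [SecretomeSet-class].
#' @param ptm a [PTMTable-class].
#' @return `data.frame` with columns `gene`, the four counts, the four
#'   `<type>_bin` factors (`none` < `low` < `medium` < `high`) and
#'   `localization`.
#' @export
ptmAnnotationMatrix <- function(sec, ptm) {
    stopifnot(is(sec, "SecretomeSet"), is(ptm, "PTMTable"))
    tab <- annotationTable(ptm)
    gset <- genes(sec)
    i <- match(gset, tab$protein)
    counts <- data.frame(
        gene = gset,
        n_glyc = ifelse(is.na(i), 0L, tab$n_glyc_sites[i]),
        o_glyc = ifelse(is.na(i), 0L, tab$o_glyc_sites[i]),
        disulfide = ifelse(is.na(i), 0L, tab$disulfide_sites[i]),
        gpi = ifelse(is.na(i), 0L, tab$gpi_sites[i]),
        stringsAsFactors = FALSE)
    for (cc in c("n_glyc", "o_glyc", "disulfide", "gpi"))
        counts[[paste0(cc, "_bin")]] <- tercileBin(counts[[cc]])
    counts$localization <- unname(sec@localization[gset])
    counts
}

## tercile discretization over nonzero counts; zeros are "none"
tercileBin <- function(x) {
    lev <- c("none", "low", "medium", "high")
    out <- rep("none", length(x))
    nz <- x[x > 0]
    if (length(nz)) {
        cuts <- stats::quantile(nz, c(1, 2) / 3)
        out[x > 0 & x <= cuts[1L]] <- "low"
        out[x > 0 & x > cuts[1L] & x <= cuts[2L]] <- "medium"
        out[x > cuts[2L]] <- "high"
    }
    factor(out, levels = lev, ordered = TRUE)
}
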