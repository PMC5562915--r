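#' Load a gene x tissue FPKM matrix from TSV
#'
#' Expects a UTF-8 tab-separated file whose header row names the tissues and
#' whose first column holds gene symbols (header cell `gene`), decimal point
#' `"."`. Duplicate gene rows are collapsed cell-wise by the maximum FPKM
#' (conservative for FPKM > 1 presence calls) with a warning.
#'
#' @param path path to the TSV file.
#' @param datasetId label tagging the expression resource (primary vs.
#'   validation); stored in the object's metadata.
#' @return A [FPKMExperiment-class].
#' @seealso [writeExpression()] for the inverse.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeExpression(FPKMExperiment(
#'   matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("t1", "t2"))), "toy"),
#'   tf)
#' loadExpression(tf, "toy")
#' @export
loadExpression <- function(path, datasetId = "primary") {
    if (!file.exists(path))
        stop("expression file not found: ", path)
    raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character",
                             quote = "")
    if (nrow(raw) == 0L || ncol(raw) < 2L)
        stop("format error: '", path,
             "' has no expression rows/tissue columns")
    gene <- as.character(raw[[1L]])
    tissueNames <- colnames(raw)[-1L]
    vals <- matrix(NA_real_, nrow(raw), length(tissueNames),
                   dimnames = list(NULL, tissueNames))
    for (j in seq_along(tissueNames)) {
        col <- raw[[j + 1L]]
        num <- suppressWarnings(as.numeric(col))
        bad <- which(is.na(num) | !is.finite(num) | num < 0)
        if (length(bad))
            stop(sprintf(
                "format error in '%s': invalid FPKM value '%s' at gene '%s', tissue '%s'",
                path, col[bad[1L]], gene[bad[1L]], tissueNames[j]))
        vals[, j] <- num
    }
    if (anyDuplicated(gene)) {
        dup <- unique(gene[duplicated(gene)])
        warning(sprintf("collapsing %d duplicated gene row(s) by max FPKM: %s",
                        length(dup),
                        paste(utils::head(dup, 5L), collapse = ", ")))
        vals <- do.call(rbind, lapply(split(seq_along(gene), gene), function(i)
            apply(vals[i, , drop = FALSE], 2L, max)))
        vals <- vals[unique(gene), , drop = FALSE]
    } else {
        rownames(vals) <- gene
    }
    FPKMExperiment(vals, datasetId = datasetId)
}

#' Write an FPKM matrix as TSV
#'
#' Inverse of [loadExpression()]: header `gene<TAB>tissue1...tissueN`, one
#' row per gene, `"."` decimal, UTF-8.
#'
#' @param x a [FPKMExperiment-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeExpression <- function(x, path) {
    stopifnot(is(x, "FPKMExperiment"))
    tab <- data.frame(gene = rownames(x), fpkm(x), check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Load the secretory-pathway annotation from TSV
#'
#' Requires columns `gene`, `module`, `subsystem`, `family`; optional
#' `secretory_client` (logical) and `complex_count` (nonnegative integer).
#' Families left with a single member become `"none"` for that gene (the
#' family-level outlier test needs >= 2 members) with a message. When a
#' controlled-vocabulary file (one subsystem label per line) is supplied,
#' unknown subsystem labels raise a validation error.
#'
#' @param path path to the annotation TSV.
#' @param subsystemVocab optional path to a text file of allowed subsystem
#'   labels.
#' @return A [PathwayAnnotation-class].
#' @export
loadPathwayAnnotation <- function(path, subsystemVocab = NULL) {
    if (!file.exists(path))
        stop("annotation file not found: ", path)
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, quote = "",
                             stringsAsFactors = FALSE)
    need <- c("gene", "module", "subsystem", "family")
    if (!all(need %in% names(tab)))
        stop("annotation must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(tab$gene))
        stop("validation error: duplicated gene entries in annotation")
    tab$family <- as.character(tab$family)
    tab$family[is.na(tab$family) | tab$family == ""] <- "none"
    if (!is.null(subsystemVocab)) {
        vocab <- readLines(subsystemVocab, warn = FALSE)
        vocab <- vocab[nzchar(vocab)]
        unknown <- setdiff(unique(tab$subsystem), vocab)
        if (length(unknown))
            stop("validation error: unknown subsystem label(s): ",
                 paste(unknown, collapse = ", "))
    }
    sizes <- table(tab$family[tab$family != "none"])
    singletons <- names(sizes)[sizes < 2L]
    if (length(singletons)) {
        message("dropping singleton famil",
                if (length(singletons) > 1L) "ies: " else "y: ",
                paste(singletons, collapse = ", "))
        tab$family[tab$family %in% singletons] <- "none"
    }
    if (!is.null(tab$secretory_client))
        tab$secretory_client <- as.logical(tab$secretory_client)
    if (!is.null(tab$complex_count))
        tab$complex_count <- as.integer(tab$complex_count)
    PathwayAnnotation(tab)
}

#' Write a pathway annotation as TSV
#'
#' @param ann a [PathwayAnnotation-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writePathwayAnnotation <- function(ann, path) {
    stopifnot(is(ann, "PathwayAnnotation"))
    utils::write.table(annotationTable(ann), path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}
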