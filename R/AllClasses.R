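#' @include AllGenerics.R
#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors metadata metadata<-
NULL

## ---------------------------------------------------------------------------
## FPKMExperiment
## ---------------------------------------------------------------------------

#' FPKMExperiment: a validated gene x tissue FPKM matrix
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single assay `"fpkm"` (genes in rows, tissues in columns) plus a dataset
#' identifier (e.g. primary vs. validation resource). Validity enforces the
#' contracts every downstream stage assumes: finite nonnegative values and
#' unique gene/tissue names.
#'
#' @slot .placeholder no additional slots; see Details.
#' @aliases FPKMExperiment
#' @export
setClass("FPKMExperiment", contains = "SummarizedExperiment")

setValidity("FPKMExperiment", function(object) {
    msg <- NULL
    if (!"fpkm" %in% assayNames(object))
        msg <- c(msg, "assay 'fpkm' is required")
    else {
        v <- assay(object, "fpkm")
        if (!is.numeric(v))
            msg <- c(msg, "FPKM values must be numeric")
        else if (anyNA(v) || any(!is.finite(v)))
            msg <- c(msg, "FPKM values must be finite and non-missing")
        else if (any(v < 0))
            msg <- c(msg, "FPKM values must be nonnegative")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene names must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "tissue names must be present and unique")
    id <- metadata(object)$datasetId
    if (is.null(id) || !is.character(id) || length(id) != 1L)
        msg <- c(msg, "metadata()$datasetId must be a single character label")
    if (is.null(msg)) TRUE else msg
})

#' Construct an FPKMExperiment
#'
#' @param fpkm numeric matrix, genes in rows (rownames = gene symbols),
#'   tissues in columns (colnames = tissue names). Values are FPKM:
#'   nonnegative and finite.
#' @param datasetId single character label identifying the expression
#'   resource, e.g. `"gtex"` (primary) or `"hpa"` (validation).
#' @return A [FPKMExperiment-class] object.
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("liver", "lung")))
#' fe <- FPKMExperiment(m, "toy")
#' datasetId(fe)
#' @export
FPKMExperiment <- function(fpkm, datasetId = "primary") {
    fpkm <- as.matrix(fpkm)
    storage.mode(fpkm) <- "double"
    se <- SummarizedExperiment(assays = list(fpkm = fpkm))
    metadata(se)$datasetId <- as.character(datasetId)
    new("FPKMExperiment", se)
}

#' @rdname datasetId
#' @export
setMethod("datasetId", "FPKMExperiment", function(x) metadata(x)$datasetId)

#' @rdname datasetId
#' @export
setReplaceMethod("datasetId", "FPKMExperiment", function(x, value) {
    metadata(x)$datasetId <- as.character(value)
    validObject(x)
    x
})

#' @rdname tissues
#' @export
setMethod("tissues", "FPKMExperiment", function(x) colnames(x))

#' @rdname genes
#' @export
setMethod("genes", "FPKMExperiment", function(x) rownames(x))

#' Extract the FPKM assay
#'
#' @param x a [FPKMExperiment-class].
#' @return Numeric matrix of FPKM values (genes x tissues).
#' @export
fpkm <- function(x) {
    stopifnot(is(x, "FPKMExperiment"))
    assay(x, "fpkm")
}

setMethod("show", "FPKMExperiment", function(object) {
    cat(sprintf("FPKMExperiment '%s': %d genes x %d tissues\n",
                datasetId(object), nrow(object), ncol(object)))
    callNextMethod()
})

## ---------------------------------------------------------------------------
## PathwayAnnotation
## ---------------------------------------------------------------------------

#' PathwayAnnotation: secretory-pathway gene annotation
#'
#' Maps each pathway gene to its functional module, subsystem and gene
#' family, with a secretory-client flag and an optional protein-complex
#' count. Families listed here are the statistical units of the extreme-gene
#' analysis; singleton families are rejected at load time (the gene is kept
#' with family `"none"`).
#'
#' @slot table `data.frame` with columns `gene`, `module`, `subsystem`,
#'   `family`, `secretory_client`, `complex_count`.
#' @export
setClass("PathwayAnnotation", representation(table = "data.frame"))

setValidity("PathwayAnnotation", function(object) {
    tab <- object@table
    need <- c("gene", "module", "subsystem", "family",
              "secretory_client", "complex_count")
    msg <- NULL
    if (!all(need %in% names(tab)))
        msg <- c(msg, paste("missing columns:",
                            paste(setdiff(need, names(tab)), collapse = ", ")))
    else {
        if (anyDuplicated(tab$gene))
            msg <- c(msg, "each gene may appear at most once")
        fam <- tab$family[tab$family != "none"]
        if (length(fam) && any(table(fam) < 2L))
            msg <- c(msg, "families must have >= 2 members (use 'none')")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a PathwayAnnotation from a data.frame
#'
#' Most users will call [loadPathwayAnnotation()] on a TSV instead.
#'
#' @param table `data.frame` with at least columns `gene`, `module`,
#'   `subsystem`, `family`; missing `secretory_client`/`complex_count` are
#'   filled with `FALSE`/`NA`.
#' @return A [PathwayAnnotation-class] object.
#' @export
PathwayAnnotation <- function(table) {
    table <- as.data.frame(table)
    if (is.null(table$secretory_client)) table$secretory_client <- FALSE
    if (is.null(table$complex_count)) table$complex_count <- NA_integer_
    table$gene <- as.character(table$gene)
    table$family <- as.character(table$family)
    table$family[is.na(table$family) | table$family == ""] <- "none"
    new("PathwayAnnotation", table = table)
}

#' @rdname annotationTable
#' @export
setMethod("annotationTable", "PathwayAnnotation", function(x) x@table)

#' @rdname genes
#' @export
setMethod("genes", "PathwayAnnotation", function(x) x@table$gene)

#' @rdname geneFamilies
#' @export
setMethod("geneFamilies", "PathwayAnnotation", function(x) {
    tab <- x@table[x@table$family != "none", , drop = FALSE]
    split(tab$gene, tab$family)
})

#' @rdname subsystems
#' @export
setMethod("subsystems", "PathwayAnnotation", function(x)
    sort(unique(x@table$subsystem)))

setMethod("show", "PathwayAnnotation", function(object) {
    fams <- geneFamilies(object)
    cat(sprintf(paste0("PathwayAnnotation: %d genes, %d subsystems, ",
                       "%d gene families (%d genes in families)\n"),
                nrow(object@table), length(subsystems(object)),
                length(fams), sum(lengths(fams))))
})

## ---------------------------------------------------------------------------
## PTMTable
## ---------------------------------------------------------------------------

#' PTMTable: per-protein post-translational modification features
#'
#' One row per protein with counts of N-/O-glycosylation sites, disulfide
#' bonds, GPI-anchor sites and transmembrane domains, a signal-peptide flag,
#' an optional unconventional-secretion (SecretomeP-style) score and a
#' localization term. Built by [parseUniprotGFF()].
#'
#' @slot table `data.frame`; see [parseUniprotGFF()] for columns.
#' @slot nSkipped number of malformed feature lines skipped at parse time.
#' @export
setClass("PTMTable",
         representation(table = "data.frame", nSkipped = "integer"))

setValidity("PTMTable", function(object) {
    tab <- object@table
    need <- c("protein", "n_glyc_sites", "o_glyc_sites", "disulfide_sites",
              "gpi_sites", "tm_domains", "has_signal_peptide",
              "secretomep_score", "localization")
    msg <- NULL
    if (!all(need %in% names(tab)))
        msg <- c(msg, paste("missing columns:",
                            paste(setdiff(need, names(tab)), collapse = ", ")))
    else {
        cnt <- c("n_glyc_sites", "o_glyc_sites", "disulfide_sites",
                 "gpi_sites", "tm_domains")
        for (cc in cnt) {
            v <- tab[[cc]]
            if (anyNA(v) || any(v < 0) || any(v != round(v)))
                msg <- c(msg, sprintf("%s must be nonnegative integers", cc))
        }
        if (anyDuplicated(tab$protein))
            msg <- c(msg, "each protein may appear at most once")
        sc <- tab$secretomep_score
        if (any(!is.na(sc) & (sc < 0 | sc > 1)))
            msg <- c(msg, "secretomep_score must lie in [0, 1] or be NA")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a PTMTable from a data.frame
#'
#' @param table `data.frame` with the columns documented in
#'   [parseUniprotGFF()]; missing optional columns are filled.
#' @param nSkipped integer count of skipped malformed lines.
#' @return A [PTMTable-class] object.
#' @export
PTMTable <- function(table, nSkipped = 0L) {
    table <- as.data.frame(table)
    defaults <- list(n_glyc_sites = 0L, o_glyc_sites = 0L,
                     disulfide_sites = 0L, gpi_sites = 0L, tm_domains = 0L,
                     has_signal_peptide = FALSE,
                     secretomep_score = NA_real_,
                     localization = NA_character_)
    for (nm in names(defaults))
        if (is.null(table[[nm]])) table[[nm]] <- defaults[[nm]]
    table$protein <- as.character(table$protein)
    new("PTMTable", table = table, nSkipped = as.integer(nSkipped))
}

#' @rdname annotationTable
#' @export
setMethod("annotationTable", "PTMTable", function(x) x@table)

setMethod("show", "PTMTable", function(object) {
    tab <- object@table
    cat(sprintf(paste0("PTMTable: %d proteins (%d with signal peptide, ",
                       "%d with >=1 disulfide bond); %d malformed lines ",
                       "skipped\n"),
                nrow(tab), sum(tab$has_signal_peptide),
                sum(tab$disulfide_sites > 0), object@nSkipped))
})

## ---------------------------------------------------------------------------
## SecretomeSet
## ---------------------------------------------------------------------------

#' SecretomeSet: the secretome analysis gene set
#'
#' Partition of annotated proteins into the conventional secretome (signal
#' peptide present; the analysis set), proteins excluded as unconventional
#' secretion candidates (no signal peptide, SecretomeP-style score > 0.6),
#' and proteins dropped as neither.
#'
#' @slot genes analysis set (conventional secretome), character.
#' @slot excluded unconventional-secretion proteins, character.
#' @slot dropped proteins matching neither filter, character.
#' @slot localization named character, localization term per analysis gene.
#' @export
setClass("SecretomeSet",
         representation(genes = "character", excluded = "character",
                        dropped = "character", localization = "character"))

#' @rdname genes
#' @export
setMethod("genes", "SecretomeSet", function(x) x@genes)

setMethod("show", "SecretomeSet", function(object) {
    cat(sprintf(paste0("SecretomeSet: %d analysis genes (conventional), ",
                       "%d excluded (unconventional), %d dropped\n"),
                length(object@genes), length(object@excluded),
                length(object@dropped)))
})

## ---------------------------------------------------------------------------
## TissueGeneNetwork
## ---------------------------------------------------------------------------

#' TissueGeneNetwork: bipartite tissue / extreme-gene network
#'
#' Strictly bipartite network connecting tissues to the genes called extreme
#' in them. Edge attributes carry the Grubbs statistic, p-value, raw-FPKM
#' fold change and the consensus-validation flag; gene nodes carry family
#' and subsystem.
#'
#' @slot edgeTable `data.frame` with columns `gene`, `tissue`, `G`, `p`,
#'   `fold_change`, `validated`.
#' @slot geneInfo `data.frame` with columns `gene`, `family`, `subsystem`.
#' @export
setClass("TissueGeneNetwork",
         representation(edgeTable = "data.frame", geneInfo = "data.frame"))

setValidity("TissueGeneNetwork", function(object) {
    msg <- NULL
    ed <- object@edgeTable
    gi <- object@geneInfo
    need <- c("gene", "tissue", "G", "p", "fold_change", "validated")
    if (!all(need %in% names(ed)))
        msg <- c(msg, "edge table must have gene/tissue/G/p/fold_change/validated")
    if (!all(c("gene", "family", "subsystem") %in% names(gi)))
        msg <- c(msg, "geneInfo must have gene/family/subsystem")
    else {
        if (anyDuplicated(gi$gene))
            msg <- c(msg, "duplicate gene nodes")
        if (nrow(gi) && !all(gi$gene %in% ed$gene))
            msg <- c(msg, "every gene node must have degree >= 1")
        if (nrow(ed) && any(ed$gene %in% ed$tissue))
            msg <- c(msg, "network must be bipartite (gene and tissue labels overlap)")
    }
    if (is.null(msg)) TRUE else msg
})

#' @rdname edges
#' @export
setMethod("edges", "TissueGeneNetwork", function(x) x@edgeTable)

#' @rdname tissues
#' @export
setMethod("tissues", "TissueGeneNetwork", function(x)
    sort(unique(x@edgeTable$tissue)))

#' @rdname genes
#' @export
setMethod("genes", "TissueGeneNetwork", function(x) x@geneInfo$gene)

setMethod("show", "TissueGeneNetwork", function(object) {
    ed <- object@edgeTable
    cat(sprintf(paste0("TissueGeneNetwork: %d gene nodes, %d tissue nodes, ",
                       "%d edges (%d validated)\n"),
                nrow(object@geneInfo), length(unique(ed$tissue)), nrow(ed),
                sum(ed$validated)))
})

## ---------------------------------------------------------------------------
## GrubbsResult
## ---------------------------------------------------------------------------

#' GrubbsResult: outcome of the Grubbs outlier statistic on one vector
#'
#' @slot G the Grubbs statistic, `max|x - mean(x)| / sd(x)`.
#' @slot n sample size.
#' @slot p two-sided p-value (NA until [grubbsPvalue()] is applied).
#' @slot argmax index of the maximal absolute deviation (lowest on ties).
#' @slot direction `"above"` or `"below"` the sample mean.
#' @export
setClass("GrubbsResult",
         representation(G = "numeric", n = "integer", p = "numeric",
                        argmax = "integer", direction = "character"))

setMethod("show", "GrubbsResult", function(object) {
    cat(sprintf("GrubbsResult: G = %.4f (n = %d, %s mean, index %d), p = %s\n",
                object@G, object@n, object@direction, object@argmax,
                if (is.na(object@p)) "NA" else format(object@p, digits = 4)))
})
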