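NULL

#' Dataset identifier of an expression object
#'
#' @param x a [FPKMExperiment-class] object.
#' @return A single character label (e.g. `"gtex"`, `"hpa"`).
#' @export
setGeneric("datasetId", function(x) standardGeneric("datasetId"))

#' @rdname datasetId
#' @param value replacement label.
#' @export
setGeneric("datasetId<-", function(x, value) standardGeneric("datasetId<-"))

#' Tissue names of an object
#'
#' @param x an object with a tissue dimension.
#' @return Character vector of tissue names.
#' @export
setGeneric("tissues", function(x) standardGeneric("tissues"))

#' Annotation table of a pathway annotation
#'
#' @param x a [PathwayAnnotation-class] or [PTMTable-class] object.
#' @return A `data.frame`, one row per gene/protein.
#' @export
setGeneric("annotationTable", function(x) standardGeneric("annotationTable"))

#' Gene families defined by an annotation
#'
#' @param x a [PathwayAnnotation-class] object.
#' @return Named list of character vectors, family name -> member genes.
#' @export
setGeneric("geneFamilies", function(x) standardGeneric("geneFamilies"))

#' Subsystem names defined by an annotation
#'
#' @param x a [PathwayAnnotation-class] object.
#' @return Character vector of distinct subsystem labels.
#' @export
setGeneric("subsystems", function(x) standardGeneric("subsystems"))

#' Edge table of a tissue-gene network
#'
#' @param x a [TissueGeneNetwork-class] object.
#' @return `data.frame` with columns gene, tissue, G, p, fold_change, validated.
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' Genes carried by an object
#'
#' @param x a sectune object with a gene dimension or gene set.
#' @return Character vector of gene symbols.
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
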