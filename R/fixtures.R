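#' Path to the packaged synthetic pathway-annotation fixture
#'
#' A synthetic secretory-pathway catalogue mirroring the published
#' catalogue's shape — 575 genes over 13 subsystems, 30 gene families with
#' sizes in 4..44 summing to 348 genes (the remainder carry family
#' `"none"`) — with synthetic gene symbols (family prefix + index). It
#' exists so the annotation loader and the family-level statistics can be
#' exercised at realistic scale; its membership does not reproduce any
#' real gene catalogue. (The source catalogue reports its family total
#' inconsistently as 347 or 348; this fixture encodes 348.)
#'
#' @return File path of the TSV, loadable with [loadPathwayAnnotation()].
#' @examples
#' ann <- loadPathwayAnnotation(annotationFixture())
#' ann
#' @export
annotationFixture <- function() {
    system.file("extdata", "secretory_pathway_annotation_synthetic.tsv",
                package = "sectune", mustWork = TRUE)
}
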