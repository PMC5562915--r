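#' Convert a TissueGeneNetwork to an igraph object
#'
#' Vertices carry `nodeType` (`"gene"`/`"tissue"`) and, for genes, `family`
#' and `subsystem`; edges carry `G`, `p`, `fold_change`, `validated`.
#'
#' @param net a [TissueGeneNetwork-class].
#' @return An [igraph::igraph] bipartite graph.
#' @export
asIgraph <- function(net) {
    stopifnot(is(net, "TissueGeneNetwork"))
    ed <- edges(net)
    gi <- net@geneInfo
    tissueNodes <- sort(unique(ed$tissue))
    verts <- data.frame(
        name = c(gi$gene, tissueNodes),
        nodeType = c(rep("gene", nrow(gi)), rep("tissue", length(tissueNodes))),
        family = c(gi$family, rep(NA_character_, length(tissueNodes))),
        subsystem = c(gi$subsystem, rep(NA_character_, length(tissueNodes))),
        stringsAsFactors = FALSE)
    el <- data.frame(from = ed$gene, to = ed$tissue,
                     G = ed$G, p = ed$p, fold_change = ed$fold_change,
                     validated = ed$validated, stringsAsFactors = FALSE)
    igraph::graph_from_data_frame(el, directed = FALSE, vertices = verts)
}

#' Export a tissue-gene network to SIF or GraphML
#'
#' SIF lines read `gene<TAB>extreme_in<TAB>tissue` (one per edge; attributes
#' are not representable in SIF). GraphML carries all node and edge
#' attributes and round-trips exactly through [readNetworkGraphML()]. An
#' empty network writes an empty file with a warning.
#'
#' @param net a [TissueGeneNetwork-class].
#' @param path output file path.
#' @param format `"sif"` or `"graphml"`.
#' @return Invisibly, `path`.
#' @export
writeNetwork <- function(net, path, format = c("sif", "graphml")) {
    stopifnot(is(net, "TissueGeneNetwork"))
    if (length(format) == 1L && !format %in% c("sif", "graphml"))
        stop("unsupported network format: ", format)
    format <- match.arg(format)
    ed <- edges(net)
    if (nrow(ed) == 0L) {
        warning("writing empty network")
        if (format == "sif") {
            writeLines(character(0L), path)
        } else {
            igraph::write_graph(igraph::make_empty_graph(directed = FALSE),
                                path, format = "graphml")
        }
        return(invisible(path))
    }
    if (format == "sif") {
        writeLines(paste(ed$gene, "extreme_in", ed$tissue, sep = "\t"), path)
    } else {
        igraph::write_graph(asIgraph(net), path, format = "graphml")
    }
    invisible(path)
}

#' Read a tissue-gene network back from GraphML
#'
#' @param path a GraphML file written by [writeNetwork()].
#' @return A [TissueGeneNetwork-class].
#' @export
readNetworkGraphML <- function(path) {
    g <- igraph::read_graph(path, format = "graphml")
    if (igraph::vcount(g) == 0L)
        return(new("TissueGeneNetwork",
                   edgeTable = emptyExtremeCalls()[
                       , c("gene", "tissue", "G", "p", "fold_change",
                           "validated")],
                   geneInfo = data.frame(gene = character(0L),
                                         family = character(0L),
                                         subsystem = character(0L))))
    va <- igraph::vertex_attr(g)
    el <- igraph::as_edgelist(g, names = TRUE)
    isGene <- va$nodeType == "gene"
    geneSet <- va$name[isGene]
    ## edges may come out in either orientation; put gene first
    flip <- !(el[, 1L] %in% geneSet)
    el[flip, ] <- el[flip, c(2L, 1L)]
    ea <- igraph::edge_attr(g)
    ed <- data.frame(gene = el[, 1L], tissue = el[, 2L],
                     G = as.numeric(ea$G), p = as.numeric(ea$p),
                     fold_change = as.numeric(ea$fold_change),
                     validated = as.logical(ea$validated),
                     stringsAsFactors = FALSE)
    gi <- data.frame(gene = va$name[isGene],
                     family = as.character(va$family[isGene]),
                     subsystem = as.character(va$subsystem[isGene]),
                     stringsAsFactors = FALSE)
    new("TissueGeneNetwork", edgeTable = ed, geneInfo = gi)
}
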