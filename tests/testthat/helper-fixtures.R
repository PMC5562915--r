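# shared fixture builders -------------------------------------------------

toyFPKM <- function(values, genes = NULL, tissues = NULL, id = "toy") {
    m <- as.matrix(values)
    if (is.null(genes))
        genes <- rownames(m) %||% sprintf("g%d", seq_len(nrow(m)))
    if (is.null(tissues))
        tissues <- colnames(m) %||% sprintf("t%d", seq_len(ncol(m)))
    dimnames(m) <- list(genes, tissues)
    FPKMExperiment(m, datasetId = id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

writeToyExpressionTSV <- function(lines) {
    path <- withr::local_tempfile(fileext = ".tsv",
                                  .local_envir = parent.frame())
    writeLines(lines, path)
    path
}

writeToyGFF <- function(lines) {
    path <- withr::local_tempfile(fileext = ".gff",
                                  .local_envir = parent.frame())
    writeLines(lines, path)
    path
}

toyAnnotation <- function(genes, family, subsystem = "Protein folding") {
    PathwayAnnotation(data.frame(
        gene = genes, module = "Folding and quality control",
        subsystem = subsystem, family = family,
        stringsAsFactors = FALSE))
}

# Monte-Carlo oracle for the Grubbs tail probability: fraction of
# standard-normal samples of size n whose statistic reaches g
mcGrubbsTail <- function(g, Gdraws) mean(Gdraws >= g)

mcGrubbsDraws <- function(n, nDraws = 1e5, seed = 42) {
    withr::with_seed(seed, {
        z <- matrix(stats::rnorm(nDraws * n), ncol = n)
        m <- rowMeans(z)
        s <- sqrt((rowSums(z^2) - n * m^2) / (n - 1))
        dev <- abs(z - m)
        do.call(pmax, as.data.frame(dev)) / s
    })
}
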