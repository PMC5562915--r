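## Feature types of interest in the UniProt GFF dialect (column 3), and how
## each contributes to a PTMRecord. "Glycosylation" rows are split into N-
## vs O-linked by the Note/description text; "Lipidation" rows count toward
## GPI anchors only when the Note mentions GPI.

#' Parse a UniProt-dialect GFF of protein features into a PTMTable
#'
#' Reads a GFF3-style 9-column file in the UniProt dialect (column 1 =
#' protein accession/symbol, column 3 = feature type, column 9 free-text
#' attributes with `Note=`). The secretory features collected are: Signal
#' peptide, Glycosylation (N- vs O-linked distinguished by the Note text),
#' Disulfide bond, Lipidation carrying a GPI anchor, and Transmembrane.
#' Each `Disulfide bond` feature line counts one toward the protein's
#' disulfide-site count (one bond, not two half-cystines). Malformed lines
#' (fewer than 9 tab-separated fields) are skipped and counted in a single
#' warning. Comment lines (`#`) and FASTA trailers are ignored.
#'
#' UniProt GFF carries no localization or unconventional-secretion score;
#' supply those through `metaPath`, a TSV with columns `protein` and any of
#' `secretomep_score` (in \[0, 1\]) and `localization`.
#'
#' @param path path to the GFF file.
#' @param metaPath optional companion TSV (see Details).
#' @return A [PTMTable-class] with columns `protein`, `n_glyc_sites`,
#'   `o_glyc_sites`, `disulfide_sites`, `gpi_sites`, `tm_domains`,
#'   `has_signal_peptide`, `secretomep_score`, `localization`.
#' @export
parseUniprotGFF <- function(path, metaPath = NULL) {
    if (!file.exists(path))
        stop("GFF file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines)) {
        fasta <- which(startsWith(lines, ">"))
        if (length(fasta)) lines <- lines[seq_len(fasta[1L] - 1L)]
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ok <- lengths(fields) >= 9L
    nSkipped <- sum(!ok)
    if (nSkipped > 0L)
        warning(sprintf("skipped %d malformed GFF line(s)", nSkipped))
    fields <- fields[ok]
    if (!length(fields))
        stop("no parsable features in '", path, "'")
    protein <- vapply(fields, `[[`, "", 1L)
    type <- vapply(fields, `[[`, "", 3L)
    note <- vapply(fields, `[[`, "", 9L)

    typeLower <- tolower(type)
    noteLower <- tolower(note)
    isSignal <- typeLower == "signal peptide" | typeLower == "signal"
    isGlyc <- typeLower == "glycosylation" |
        typeLower == "glycosylation site"
    isNGlyc <- isGlyc & grepl("n-linked", noteLower, fixed = TRUE)
    isOGlyc <- isGlyc & grepl("o-linked", noteLower, fixed = TRUE)
    isDisulfide <- typeLower == "disulfide bond"
    isGPI <- (typeLower == "lipidation" & grepl("gpi", noteLower)) |
        typeLower == "gpi-anchor" | typeLower == "gpi-anchor amidation"
    isTM <- typeLower == "transmembrane" | typeLower == "transmembrane region"

    keep <- isSignal | isGlyc | isDisulfide | isGPI | isTM
    if (!any(keep))
        stop("no secretory features found in '", path, "'")
    prot <- sort(unique(protein[keep]))
    countBy <- function(flag) {
        tt <- table(factor(protein[flag], levels = prot))
        as.integer(tt)
    }
    tab <- data.frame(
        protein = prot,
        n_glyc_sites = countBy(isNGlyc),
        o_glyc_sites = countBy(isOGlyc),
        disulfide_sites = countBy(isDisulfide),
        gpi_sites = countBy(isGPI),
        tm_domains = countBy(isTM),
        has_signal_peptide = as.integer(countBy(isSignal)) > 0L,
        secretomep_score = NA_real_,
        localization = NA_character_,
        stringsAsFactors = FALSE)

    if (!is.null(metaPath)) {
        meta <- utils::read.delim(metaPath, header = TRUE, sep = "\t",
                                  quote = "", stringsAsFactors = FALSE)
        if (!"protein" %in% names(meta))
            stop("companion table must have a 'protein' column")
        i <- match(tab$protein, meta$protein)
        if ("secretomep_score" %in% names(meta))
            tab$secretomep_score <- as.numeric(meta$secretomep_score)[i]
        if ("localization" %in% names(meta))
            tab$localization <- as.character(meta$localization)[i]
    }
    PTMTable(tab, nSkipped = nSkipped)
}
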