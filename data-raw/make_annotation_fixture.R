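## Deterministically regenerates the synthetic secretory-pathway annotation
## fixture at inst/extdata/secretory_pathway_annotation_synthetic.tsv.
## The fixture mirrors the published catalogue's *shape* only: 575 genes,
## 13 subsystems, 30 gene families with sizes in 4..44 summing to 348
## (the remaining 227 genes carry family "none"). Gene symbols are
## synthetic (family prefix + index); membership does not reproduce any
## real catalogue. Run from the package root:
##   Rscript data-raw/make_annotation_fixture.R

famSizes <- c(44L, 24L, 20L, 19L, 18L, 16L, 14L, 13L, 12L, 12L, 11L, 11L,
              10L, 10L, 10L, 9L, 9L, 9L, 8L, 8L, 8L, 7L, 7L, 7L, 6L, 6L,
              6L, 5L, 5L, 4L)
famNames <- c("RAB", "SEC", "TBC", "DNAJ", "VPS", "STX", "GALNT", "ARF",
              "SNX", "TMED", "GOLGA", "TRAPPC", "COG", "EXOC", "PIG",
              "MGAT", "FUT", "CHST", "PDI", "SRP", "VAMP", "B4GALT",
              "ST6GAL", "SNAP", "DERL", "EDEM", "KDELR", "SAR", "UGGT",
              "OST")
stopifnot(length(famSizes) == 30L, sum(famSizes) == 348L,
          all(famSizes >= 4L), all(famSizes <= 44L))

famSubsystem <- c(
    RAB = "Post-Golgi trafficking", SEC = "COPII budding",
    TBC = "Trafficking regulation", DNAJ = "Protein folding",
    VPS = "Post-Golgi trafficking", STX = "Exocytosis",
    GALNT = "Golgi glycosylation", ARF = "Trafficking regulation",
    SNX = "Clathrin vesicles", TMED = "COPI retrieval",
    GOLGA = "Post-Golgi trafficking", TRAPPC = "COPII budding",
    COG = "Golgi glycosylation", EXOC = "Exocytosis",
    PIG = "GPI biosynthesis", MGAT = "Golgi glycosylation",
    FUT = "Golgi glycosylation", CHST = "Golgi glycosylation",
    PDI = "Protein folding", SRP = "Translocation",
    VAMP = "Exocytosis", B4GALT = "Golgi glycosylation",
    ST6GAL = "Golgi glycosylation", SNAP = "Exocytosis",
    DERL = "ERAD", EDEM = "ERAD", KDELR = "COPI retrieval",
    SAR = "COPII budding", UGGT = "ER glycosylation",
    OST = "ER glycosylation")

subsystems <- c(
    "Translocation", "Protein folding", "ERAD", "ER glycosylation",
    "Golgi glycosylation", "GPI biosynthesis", "COPII budding",
    "COPI retrieval", "Clathrin vesicles", "Post-Golgi trafficking",
    "Trafficking regulation", "Exocytosis", "Unfolded protein response")
moduleOf <- c(
    "Translocation" = "Entry and translocation",
    "Protein folding" = "Folding and quality control",
    "ERAD" = "Folding and quality control",
    "Unfolded protein response" = "Folding and quality control",
    "ER glycosylation" = "Glycosylation and PTM",
    "Golgi glycosylation" = "Glycosylation and PTM",
    "GPI biosynthesis" = "Glycosylation and PTM",
    "COPII budding" = "Trafficking",
    "COPI retrieval" = "Trafficking",
    "Clathrin vesicles" = "Trafficking",
    "Post-Golgi trafficking" = "Trafficking",
    "Trafficking regulation" = "Trafficking",
    "Exocytosis" = "Trafficking")

famRows <- do.call(rbind, lapply(seq_along(famNames), function(i) {
    data.frame(gene = sprintf("%s%d", famNames[i], seq_len(famSizes[i])),
               subsystem = famSubsystem[[famNames[i]]],
               family = famNames[i], stringsAsFactors = FALSE)
}))

nSingle <- 575L - nrow(famRows)
singleRows <- data.frame(
    gene = sprintf("SPC%03d", seq_len(nSingle)),
    subsystem = subsystems[(seq_len(nSingle) - 1L) %% 13L + 1L],
    family = "none", stringsAsFactors = FALSE)

tab <- rbind(famRows, singleRows)
tab$module <- moduleOf[tab$subsystem]
tab$secretory_client <- seq_len(nrow(tab)) %% 5L == 0L
tab$complex_count <- ifelse(seq_len(nrow(tab)) %% 3L == 0L,
                            seq_len(nrow(tab)) %% 7L, NA_integer_)
tab <- tab[, c("gene", "module", "subsystem", "family",
               "secretory_client", "complex_count")]
stopifnot(nrow(tab) == 575L, !anyDuplicated(tab$gene),
          length(unique(tab$subsystem)) == 13L,
          length(unique(tab$family[tab$family != "none"])) == 30L)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write.table(tab,
            "inst/extdata/secretory_pathway_annotation_synthetic.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE,
            fileEncoding = "UTF-8")
cat("wrote", nrow(tab), "genes\n")
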