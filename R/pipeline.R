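## Stage orchestrator: runs the analysis stages in dependency order on
## files in the dialects the loaders read, with a provenance record
## (config + package version + seed) written alongside the outputs. Every
## stage is individually re-runnable from the intermediate files.

defaultConfig <- function() {
    list(outDir = ".",
         expressionPrimary = NULL, expressionValidation = NULL,
         annotation = NULL, ptmGff = NULL, ptmMeta = NULL,
         aliasMap = NULL,
         alpha = 0.05, logTransform = TRUE, nPerm = 999L, seed = 1L,
         iterate = FALSE, maxDepth = 2L, bhCorrect = FALSE,
         minFamilySize = 3L, wholeSecretome = FALSE,
         referenceTissue = NULL, group = NULL)
}

#' Run pipeline stages on input files
#'
#' Subcommands: `"simulate"` (write a fixture bundle from [tinyPlan()] or a
#' plan YAML), `"classify"` (six-category calls), `"correlate"`
#' (cross-tissue correlation, clustering, Newick tree, optional
#' permutation test), `"families"` (per-family correlation profiles),
#' `"extreme"` (Grubbs calls + two-dataset consensus), `"ptm-load"`
#' (secretome, DS_e, enzyme-family regressions), `"network"` (SIF +
#' GraphML from validated calls) and `"all"` (every stage in dependency
#' order). Config values override the built-in defaults; every run writes
#' `provenance_<subcommand>.json` (config, package version, seed, time)
#' into the output directory.
#'
#' @param subcommand one of the stage names above.
#' @param config named list of config overrides; see `Details`. Unknown
#'   keys raise an error.
#' @return Invisibly, a named list of written output paths.
#' @export
runPipeline <- function(subcommand = c("all", "simulate", "classify",
                                       "correlate", "families", "extreme",
                                       "ptm-load", "network"),
                        config = list()) {
    subcommand <- match.arg(subcommand)
    cfg <- defaultConfig()
    unknown <- setdiff(names(config), c(names(cfg), "plan"))
    if (length(unknown))
        stop("invalid config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(config)] <- config
    outDir <- cfg$outDir
    if (!dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    outputs <- list()

    if (subcommand %in% c("simulate", "all")) {
        plan <- if (!is.null(config$plan)) config$plan
                else tinyPlan(seed = cfg$seed)
        outputs$bundle <- emitFixtureBundle(plan, outDir)
        ## downstream stages of "all" consume the bundle just written
        if (subcommand == "all") {
            cfg$expressionPrimary <- file.path(outDir,
                                               "expression_primary.tsv")
            cfg$expressionValidation <-
                file.path(outDir, "expression_validation.tsv")
            cfg$annotation <- file.path(outDir, "annotation.tsv")
            cfg$ptmGff <- file.path(outDir, "ptm_features.gff")
            cfg$ptmMeta <- file.path(outDir, "ptm_meta.tsv")
        }
    }

    needFile <- function(path, what) {
        if (is.null(path) || !file.exists(path))
            stop("missing input for ", what, ": ",
                 if (is.null(path)) "(not configured)" else path)
        path
    }

    loadPrimary <- function()
        loadExpression(needFile(cfg$expressionPrimary, "expression"),
                       datasetId = "primary")
    loadAnn <- function()
        loadPathwayAnnotation(needFile(cfg$annotation, "annotation"))

    if (subcommand %in% c("classify", "all")) {
        m <- loadPrimary()
        calls <- classifyAll(m)
        outputs$categories <- file.path(outDir, "categories.tsv")
        writeCategoryCalls(calls, outputs$categories)
    }

    if (subcommand %in% c("correlate", "all")) {
        m <- loadPrimary()
        ann <- loadAnn()
        rho <- crossTissueCorrelation(m, genes(ann),
                                      logTransform = cfg$logTransform,
                                      geneSetId = "pathway")
        cl <- clusterTissues(rho)
        long <- data.frame(
            tissue1 = rownames(rho)[row(rho)[upper.tri(rho)]],
            tissue2 = colnames(rho)[col(rho)[upper.tri(rho)]],
            rho = rho[upper.tri(rho)], gene_set_id = "pathway")
        outputs$correlation <- file.path(outDir, "correlation.tsv")
        utils::write.table(long, outputs$correlation, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        outputs$dendrogram <- file.path(outDir, "tissue_dendrogram.nwk")
        writeLines(cl$newick, outputs$dendrogram)
        group <- cfg$group
        if (is.null(group)) {
            ## default: the smaller branch of the 2-group split
            tabg <- table(cl$groups)
            group <- names(cl$groups)[cl$groups ==
                                      names(tabg)[which.min(tabg)]]
        }
        pt <- lowGroupPermutationTest(m, genes(ann), group,
                                      nPerm = cfg$nPerm, seed = cfg$seed,
                                      logTransform = cfg$logTransform)
        outputs$permutation <- file.path(outDir, "low_group_test.tsv")
        utils::write.table(
            data.frame(group = paste(sort(group), collapse = ","),
                       median_rho = pt$medianRho, p = pt$p,
                       n_perm = pt$nPerm),
            outputs$permutation, sep = "\t", quote = FALSE,
            row.names = FALSE)
    }

    if (subcommand %in% c("families", "all")) {
        m <- loadPrimary()
        ann <- loadAnn()
        prof <- familyCorrelationProfiles(
            m, ann, referenceTissue = cfg$referenceTissue,
            minFamilySize = cfg$minFamilySize)
        outputs$familyProfiles <- file.path(outDir, "family_profiles.tsv")
        utils::write.table(prof, outputs$familyProfiles, sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }

    consensus <- NULL
    if (subcommand %in% c("extreme", "network", "all")) {
        m <- loadPrimary()
        ann <- loadAnn()
        callsP <- detectExtremeGenes(m, ann, alpha = cfg$alpha,
                                     iterate = cfg$iterate,
                                     maxDepth = cfg$maxDepth,
                                     bhCorrect = cfg$bhCorrect,
                                     minFamilySize = cfg$minFamilySize)
        if (!is.null(cfg$expressionValidation)) {
            mv <- loadExpression(cfg$expressionValidation,
                                 datasetId = "validation")
            callsV <- detectExtremeGenes(mv, ann, alpha = cfg$alpha,
                                         iterate = cfg$iterate,
                                         maxDepth = cfg$maxDepth,
                                         bhCorrect = cfg$bhCorrect,
                                         minFamilySize = cfg$minFamilySize)
            consensus <- consensusCalls(callsP, callsV,
                                        aliasMap = cfg$aliasMap)
        } else {
            consensus <- callsP
            consensus$validated <- NA
        }
        if (subcommand != "network") {
            outputs$extremeCalls <- file.path(outDir, "extreme_calls.tsv")
            writeExtremeCalls(consensus, outputs$extremeCalls)
        }
    }

    if (subcommand %in% c("network", "all")) {
        keep <- if (any(consensus$validated %in% TRUE))
            consensus[consensus$validated %in% TRUE, , drop = FALSE]
        else consensus
        net <- buildNetwork(keep, loadAnn())
        outputs$networkSif <- file.path(outDir, "network.sif")
        outputs$networkGraphml <- file.path(outDir, "network.graphml")
        writeNetwork(net, outputs$networkSif, "sif")
        writeNetwork(net, outputs$networkGraphml, "graphml")
    }

    if (subcommand %in% c("ptm-load", "all")) {
        m <- loadPrimary()
        ptm <- parseUniprotGFF(needFile(cfg$ptmGff, "PTM GFF"),
                               metaPath = cfg$ptmMeta)
        cats <- if (cfg$wholeSecretome) NULL else classifyAll(m)
        sec <- defineSecretome(ptm, categories = cats)
        loads <- disulfideEnrichment(m, sec, ptm)
        outputs$dsLoads <- file.path(outDir, "ds_load.tsv")
        utils::write.table(loads, outputs$dsLoads, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        ann <- tryCatch(loadAnn(), error = function(e) NULL)
        if (!is.null(ann)) {
            fams <- geneFamilies(ann)
            assoc <- do.call(rbind, lapply(names(fams), function(f) {
                a <- tryCatch(
                    associateFamilyWithLoad(m, fams[[f]], loads),
                    error = function(e) NULL)
                if (!is.null(a)) a$family <- f
                a
            }))
            if (!is.null(assoc)) {
                outputs$loadAssociations <-
                    file.path(outDir, "load_associations.tsv")
                utils::write.table(assoc, outputs$loadAssociations,
                                   sep = "\t", quote = FALSE,
                                   row.names = FALSE)
            }
        }
    }

    prov <- file.path(outDir,
                      sprintf("provenance_%s.json", subcommand))
    jsonlite::write_json(
        list(subcommand = subcommand,
             config = cfg[!vapply(cfg, is.null, TRUE)],
             package = "sectune",
             version = as.character(utils::packageVersion("sectune")),
             time = format(Sys.time(), tz = "UTC")),
        prov, auto_unbox = TRUE, null = "null")
    outputs$provenance <- prov
    invisible(outputs)
}
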