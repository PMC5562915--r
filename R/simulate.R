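## Seeded generator for ground-truthed inputs: two replicate FPKM matrices
## with log-normal baselines and gene-family structure, planted
## tissue-specific spikes, a planted low-correlation tissue group, category
## plants satisfying each classification rule with margin, a synthetic
## secretome with negative-binomial PTM site counts, and an enzyme family
## whose expression tracks the tissue disulfide load linearly.

SUBSYSTEM_NAMES <- c(
    "Translocation", "Protein folding", "ERAD", "ER glycosylation",
    "Golgi glycosylation", "GPI biosynthesis", "COPII budding",
    "COPI retrieval", "Clathrin vesicles", "Post-Golgi trafficking",
    "Trafficking regulation", "Exocytosis", "Unfolded protein response")

MODULE_OF_SUBSYSTEM <- c(
    "Translocation" = "Entry and translocation",
    "Protein folding" = "Folding and quality control",
    "ERAD" = "Folding and quality control",
    "ER glycosylation" = "Glycosylation and PTM",
    "Golgi glycosylation" = "Glycosylation and PTM",
    "GPI biosynthesis" = "Glycosylation and PTM",
    "COPII budding" = "Trafficking",
    "COPI retrieval" = "Trafficking",
    "Clathrin vesicles" = "Trafficking",
    "Post-Golgi trafficking" = "Trafficking",
    "Trafficking regulation" = "Trafficking",
    "Exocytosis" = "Trafficking",
    "Unfolded protein response" = "Folding and quality control")

#' SimulationPlan: parameters of the synthetic-data generator
#'
#' Construct with [SimulationPlan()]; all outputs of [simulateSecData()]
#' are fully determined by the plan (including its `seed`).
#'
#' @slot nTissues number of tissues.
#' @slot families `data.frame(name, size)` of pathway gene families.
#' @slot nBackground non-pathway background genes (permutation-null pool).
#' @slot nPathwaySingletons pathway genes outside any family (family
#'   `"none"`), mirroring the real catalogue where roughly 40% of pathway
#'   genes are not family members; they enter the pathway gene set of the
#'   correlation analyses but not the family-level outlier test.
#' @slot baselineLocMean,baselineLocSd log-normal location hyperparameters
#'   (natural-log scale): gene-level for background/secretome genes,
#'   family-level for pathway genes.
#' @slot familyLocSd within-family spread of member baselines around the
#'   family-level location (keeps families from being dominated by a
#'   single member, as the family-share normalization assumes).
#' @slot tissueSd sd of the tissue-level log-scale component shared by the
#'   two datasets.
#' @slot replicateNoiseSd sd of the per-dataset log-scale noise
#'   distinguishing the primary and validation matrices.
#' @slot nSpikes,spikeFold planted tissue-specific expression spikes
#'   (fold > 1) placed on distinct family genes; `spikes` may give explicit
#'   `(gene, tissue, fold)` rows instead.
#' @slot spikes explicit spike table (0 rows = place `nSpikes` randomly).
#' @slot lowGroupSize,lowGroupEffectSd planted low-correlation tissue
#'   group: the group's tissues receive an independent per-gene log offset
#'   (sd `lowGroupEffectSd`) for all pathway genes.
#' @slot categoryQuota genes planted per expression category (0 disables;
#'   requires `nTissues >= 10`).
#' @slot enzymeFamilyName,enzymeSize,enzymeSlope,enzymeNoiseFrac the
#'   processing-enzyme family tied to the disulfide load:
#'   `FPKM = slope * DS_e(t) + intercept + N(0, enzymeNoiseFrac * slope *
#'   range(DS_e))`; `enzymeSize = 0` disables.
#' @slot nSecretome,secretomeTissueSd,fracSignalPeptide synthetic secretome
#'   clients and the fraction carrying a signal peptide.
#' @slot dsMean,dsDispersion negative-binomial disulfide-site counts
#'   (mean, dispersion; size = 1/dispersion).
#' @slot seed integer master seed (structure stream; per-dataset noise
#'   streams derive as seed + 1, seed + 2).
#' @export
setClass("SimulationPlan", representation(
    nTissues = "integer", families = "data.frame", nBackground = "integer",
    nPathwaySingletons = "integer",
    baselineLocMean = "numeric", baselineLocSd = "numeric",
    familyLocSd = "numeric",
    tissueSd = "numeric", replicateNoiseSd = "numeric",
    nSpikes = "integer", spikeFold = "numeric", spikes = "data.frame",
    lowGroupSize = "integer", lowGroupEffectSd = "numeric",
    categoryQuota = "integer",
    enzymeFamilyName = "character", enzymeSize = "integer",
    enzymeSlope = "numeric", enzymeNoiseFrac = "numeric",
    nSecretome = "integer", secretomeTissueSd = "numeric",
    fracSignalPeptide = "numeric",
    dsMean = "numeric", dsDispersion = "numeric",
    seed = "integer"))

setValidity("SimulationPlan", function(object) {
    msg <- NULL
    if (object@nTissues < 2L)
        msg <- c(msg, "need at least 2 tissues")
    if (nrow(object@families)) {
        if (!all(c("name", "size") %in% names(object@families)))
            msg <- c(msg, "families needs columns name, size")
        else if (object@nSpikes > 0L && any(object@families$size < 3L))
            msg <- c(msg, "spiked plans need family sizes >= 3")
    }
    if (object@spikeFold <= 1 ||
        (nrow(object@spikes) && any(object@spikes$fold <= 1)))
        msg <- c(msg, "spike folds must be > 1")
    if (object@categoryQuota > 0L && object@nTissues < 10L)
        msg <- c(msg, paste("category plants need >= 10 tissues (a",
                            "tissue-enhanced profile in fewer tissues is",
                            "always group-enriched under the greedy",
                            "prefix search)"))
    if (object@lowGroupSize >= object@nTissues)
        msg <- c(msg, "low-correlation group must be a proper tissue subset")
    if (object@enzymeSize > 0L && object@nSecretome == 0L)
        msg <- c(msg, "enzyme family requires a secretome (nSecretome > 0)")
    if (is.null(msg)) TRUE else msg
})

#' @rdname SimulationPlan-class
#' @param nTissues,families,nBackground,nPathwaySingletons,baselineLocMean,baselineLocSd,familyLocSd,tissueSd,replicateNoiseSd,nSpikes,spikeFold,spikes,lowGroupSize,lowGroupEffectSd,categoryQuota,enzymeFamilyName,enzymeSize,enzymeSlope,enzymeNoiseFrac,nSecretome,secretomeTissueSd,fracSignalPeptide,dsMean,dsDispersion,seed see the class slots.
#' @return A [SimulationPlan-class] object.
#' @export
SimulationPlan <- function(nTissues = 20L,
                           families = data.frame(
                               name = sprintf("GF%02d", 1:10),
                               size = c(4:12, 8L)),
                           nBackground = 500L, nPathwaySingletons = 60L,
                           baselineLocMean = 1, baselineLocSd = 1.2,
                           familyLocSd = 0.5,
                           tissueSd = 0.25, replicateNoiseSd = 0.35,
                           nSpikes = 15L, spikeFold = 10,
                           spikes = data.frame(gene = character(0L),
                                               tissue = character(0L),
                                               fold = numeric(0L)),
                           lowGroupSize = 5L, lowGroupEffectSd = 1.4,
                           categoryQuota = 10L,
                           enzymeFamilyName = "PDI", enzymeSize = 4L,
                           enzymeSlope = 3, enzymeNoiseFrac = 0.1,
                           nSecretome = 100L, secretomeTissueSd = 1,
                           fracSignalPeptide = 0.7,
                           dsMean = 6, dsDispersion = 1,
                           seed = 1L) {
    new("SimulationPlan",
        nTissues = as.integer(nTissues), families = families,
        nBackground = as.integer(nBackground),
        nPathwaySingletons = as.integer(nPathwaySingletons),
        baselineLocMean = baselineLocMean, baselineLocSd = baselineLocSd,
        familyLocSd = familyLocSd,
        tissueSd = tissueSd, replicateNoiseSd = replicateNoiseSd,
        nSpikes = as.integer(nSpikes), spikeFold = spikeFold,
        spikes = spikes,
        lowGroupSize = as.integer(lowGroupSize),
        lowGroupEffectSd = lowGroupEffectSd,
        categoryQuota = as.integer(categoryQuota),
        enzymeFamilyName = enzymeFamilyName,
        enzymeSize = as.integer(enzymeSize), enzymeSlope = enzymeSlope,
        enzymeNoiseFrac = enzymeNoiseFrac,
        nSecretome = as.integer(nSecretome),
        secretomeTissueSd = secretomeTissueSd,
        fracSignalPeptide = fracSignalPeptide,
        dsMean = dsMean, dsDispersion = dsDispersion,
        seed = as.integer(seed))
}

#' A tiny smoke-test plan
#'
#' 8 tissues, 3 small families, a small secretome; category plants are off
#' (they need >= 10 tissues). Runs the full pipeline in seconds.
#'
#' @param seed master seed.
#' @return A [SimulationPlan-class].
#' @export
tinyPlan <- function(seed = 1L) {
    SimulationPlan(nTissues = 8L,
                   families = data.frame(name = c("GF01", "GF02", "GF03"),
                                         size = c(4L, 5L, 6L)),
                   nBackground = 40L, nPathwaySingletons = 6L,
                   nSpikes = 2L, lowGroupSize = 3L,
                   categoryQuota = 0L, enzymeSize = 3L, nSecretome = 40L,
                   seed = seed)
}

## ---- category plant templates (deterministic shapes + jitter) -----------

plantCategoryVector <- function(category, n, idx) {
    ## n = number of tissues; idx cycles plant variants; returns unnamed
    ## vector in an arbitrary tissue order (caller permutes)
    r <- function(k, lo, hi) stats::runif(k, lo, hi)
    switch(category,
        NotDetected = r(n, 0.05, 0.8),
        TissueEnriched = c(r(1, 40, 60), r(n - 1L, 1.5, 6)),
        GroupEnriched = {
            gsize <- 2L + (idx %% 3L)
            c(r(gsize, 27, 33), r(n - gsize, 1.5, 4.5))
        },
        ExpressedInAll = r(n, 3, 6),
        TissueEnhanced = {
            tmpl <- c(1, 0.2223, 0.1345, 0.0996, 0.0801, 0.0676,
                      0.0589, 0.0523)
            scale <- r(1, 80, 120)
            c(tmpl * scale, r(n - 8L, 2.2, 2.8))
        },
        Mixed = {
            k <- 1L + (idx %% min(6L, n - 2L))
            c(r(k, 1.5, 2.2), r(n - k, 0.5, 0.9))
        },
        stop("unknown category: ", category))
}

## ---- the generator -------------------------------------------------------

#' Generate ground-truthed synthetic inputs
#'
#' Produces two replicate FPKM matrices (primary + validation), a pathway
#' annotation, a PTM table for the synthetic secretome and a ground-truth
#' record, all fully determined by the plan's seed. See
#' [SimulationPlan-class] for the generative model.
#'
#' @param plan a [SimulationPlan-class].
#' @return A list with elements `primary` and `validation`
#'   ([FPKMExperiment-class]), `annotation` ([PathwayAnnotation-class]),
#'   `ptm` ([PTMTable-class]) and `truth` (list: `spikes`, `categories`,
#'   `lowGroup`, `enzymeGenes`, `enzymeSlope`, `dsLoads`).
#' @export
simulateSecData <- function(plan) {
    validObject(plan)
    nT <- plan@nTissues
    tissueNames <- sprintf("tissue_%02d", seq_len(nT))

    famTab <- plan@families
    famGenes <- if (nrow(famTab)) {
        unlist(lapply(seq_len(nrow(famTab)), function(i)
            sprintf("%s_%d", famTab$name[i], seq_len(famTab$size[i]))))
    } else character(0L)
    famOf <- if (nrow(famTab))
        rep(famTab$name, famTab$size) else character(0L)
    enzymeGenes <- if (plan@enzymeSize > 0L)
        sprintf("%s_%d", plan@enzymeFamilyName, seq_len(plan@enzymeSize))
    else character(0L)
    singleGenes <- if (plan@nPathwaySingletons > 0L)
        sprintf("SPG%03d", seq_len(plan@nPathwaySingletons)) else character(0L)
    bgGenes <- if (plan@nBackground > 0L)
        sprintf("BG%04d", seq_len(plan@nBackground)) else character(0L)
    secGenes <- if (plan@nSecretome > 0L)
        sprintf("SECG%04d", seq_len(plan@nSecretome)) else character(0L)
    catNames <- CATEGORY_LEVELS
    plantGenes <- if (plan@categoryQuota > 0L)
        unlist(lapply(catNames, function(cc)
            sprintf("CP_%s_%02d", cc, seq_len(plan@categoryQuota))))
    else character(0L)

    pathwayGenes <- c(famGenes, enzymeGenes, singleGenes)
    noisyGenes <- c(famGenes, enzymeGenes, singleGenes, bgGenes, secGenes)
    allGenes <- c(noisyGenes, plantGenes)

    ## ---- structure stream: everything shared by the two datasets
    st <- withr::with_seed(plan@seed, {
        ## pathway genes: family-level location + within-family member
        ## offset; background/secretome genes: independent locations
        famOfAll <- c(famOf, rep(plan@enzymeFamilyName,
                                 length(enzymeGenes)))
        famLevels <- unique(famOfAll)
        famLoc <- stats::rnorm(length(famLevels), plan@baselineLocMean,
                               plan@baselineLocSd)
        names(famLoc) <- famLevels
        locFamily <- famLoc[famOfAll] +
            stats::rnorm(length(famOfAll), 0, plan@familyLocSd)
        locOther <- stats::rnorm(length(singleGenes) + length(bgGenes) +
                                 length(secGenes),
                                 plan@baselineLocMean, plan@baselineLocSd)
        loc <- c(locFamily, locOther)
        names(loc) <- noisyGenes
        lowGroup <- if (plan@lowGroupSize > 0L)
            sort(sample(tissueNames, plan@lowGroupSize)) else character(0L)
        delta <- stats::rnorm(length(pathwayGenes), 0, plan@lowGroupEffectSd)
        names(delta) <- pathwayGenes
        zShared <- matrix(stats::rnorm(length(noisyGenes) * nT), ncol = nT,
                          dimnames = list(noisyGenes, tissueNames))
        spikes <- plan@spikes
        if (nrow(spikes) == 0L && plan@nSpikes > 0L) {
            if (plan@nSpikes > length(famGenes))
                stop("plan error: more spikes than family genes")
            sg <- sample(famGenes, plan@nSpikes)
            spikes <- data.frame(gene = sg,
                                 tissue = sample(tissueNames, plan@nSpikes,
                                                 replace = TRUE),
                                 fold = plan@spikeFold,
                                 stringsAsFactors = FALSE)
        }
        plants <- NULL
        if (plan@categoryQuota > 0L) {
            plants <- matrix(NA_real_, length(plantGenes), nT,
                             dimnames = list(plantGenes, tissueNames))
            i <- 0L
            for (cc in catNames) for (q in seq_len(plan@categoryQuota)) {
                i <- i + 1L
                vec <- plantCategoryVector(cc, nT, q - 1L)
                plants[i, sample.int(nT)] <- vec
            }
        }
        ds <- if (plan@nSecretome > 0L) {
            d <- stats::rnbinom(plan@nSecretome, size = 1 / plan@dsDispersion,
                                mu = plan@dsMean)
            names(d) <- secGenes
            d
        } else integer(0L)
        nSP <- round(plan@fracSignalPeptide * plan@nSecretome)
        hasSP <- c(rep(TRUE, nSP), rep(FALSE, plan@nSecretome - nSP))
        score <- rep(NA_real_, plan@nSecretome)
        if (plan@nSecretome > nSP) {
            nonSP <- seq.int(nSP + 1L, plan@nSecretome)
            half <- nonSP[seq_len(ceiling(length(nonSP) / 2))]
            score[half] <- stats::runif(length(half), 0.65, 0.95)
            score[setdiff(nonSP, half)] <-
                stats::runif(length(setdiff(nonSP, half)), 0.05, 0.55)
        }
        ng <- if (plan@nSecretome > 0L)
            stats::rnbinom(plan@nSecretome, size = 1, mu = 3) else integer(0L)
        og <- if (plan@nSecretome > 0L)
            stats::rnbinom(plan@nSecretome, size = 1, mu = 1) else integer(0L)
        gpi <- if (plan@nSecretome > 0L)
            stats::rbinom(plan@nSecretome, 1, 0.1) else integer(0L)
        tm <- if (plan@nSecretome > 0L)
            stats::rpois(plan@nSecretome, 0.8) else integer(0L)
        localization <- if (plan@nSecretome > 0L)
            sample(c("Secreted", "Cell membrane", "ER", "Golgi"),
                   plan@nSecretome, replace = TRUE) else character(0L)
        enzymeIntercept <- stats::runif(max(plan@enzymeSize, 0L), 0, 2)
        list(loc = loc, lowGroup = lowGroup, delta = delta,
             zShared = zShared, spikes = spikes, plants = plants, ds = ds,
             hasSP = hasSP, score = score, ng = ng, og = og, gpi = gpi,
             tm = tm, localization = localization,
             enzymeIntercept = enzymeIntercept)
    })

    buildLog <- function() {
        lg <- matrix(rep(st$loc, nT), ncol = nT,
                     dimnames = list(noisyGenes, tissueNames))
        if (length(st$lowGroup) && length(pathwayGenes))
            lg[pathwayGenes, st$lowGroup] <-
                lg[pathwayGenes, st$lowGroup] + st$delta[pathwayGenes]
        secIdx <- rownames(lg) %in% secGenes
        sdRow <- ifelse(secIdx, plan@secretomeTissueSd, plan@tissueSd)
        lg + st$zShared * sdRow
    }
    sharedLog <- buildLog()

    oneDataset <- function(noiseSeed, id, dsLoads = NULL) {
        noise <- withr::with_seed(noiseSeed, matrix(
            stats::rnorm(length(noisyGenes) * nT, 0, plan@replicateNoiseSd),
            ncol = nT, dimnames = list(noisyGenes, tissueNames)))
        v <- exp(sharedLog + noise)
        for (i in seq_len(nrow(st$spikes)))
            v[st$spikes$gene[i], st$spikes$tissue[i]] <-
                v[st$spikes$gene[i], st$spikes$tissue[i]] * st$spikes$fold[i]
        if (!is.null(dsLoads) && length(enzymeGenes)) {
            rng <- diff(range(dsLoads))
            sdE <- plan@enzymeNoiseFrac * plan@enzymeSlope * max(rng, 1e-8)
            eps <- withr::with_seed(noiseSeed + 10L, matrix(
                stats::rnorm(length(enzymeGenes) * nT, 0, sdE), ncol = nT))
            for (j in seq_along(enzymeGenes))
                v[enzymeGenes[j], ] <- pmax(
                    0, plan@enzymeSlope * dsLoads + st$enzymeIntercept[j] +
                       eps[j, ])
        }
        if (!is.null(st$plants))
            v <- rbind(v, st$plants)
        FPKMExperiment(v[allGenes, , drop = FALSE], datasetId = id)
    }

    ## per-tissue disulfide load from the (primary, pre-enzyme) secretome
    dsLoads <- NULL
    if (plan@nSecretome > 0L && plan@enzymeSize > 0L) {
        pre <- oneDataset(plan@seed + 1L, "pre")
        spGenes <- secGenes[st$hasSP]
        load <- colSums(fpkm(pre)[spGenes, , drop = FALSE] * st$ds[spGenes])
        if (any(load <= 0))
            stop("plan error: zero disulfide load in some tissue")
        dsLoads <- log10(load)
    }

    primary <- oneDataset(plan@seed + 1L, "primary", dsLoads)
    validation <- oneDataset(plan@seed + 2L, "validation", dsLoads)

    annTab <- NULL
    if (length(pathwayGenes)) {
        famAll <- c(famOf, rep(plan@enzymeFamilyName, length(enzymeGenes)))
        subsysFam <- SUBSYSTEM_NAMES[
            (match(famAll, unique(famAll)) - 1L) %% length(SUBSYSTEM_NAMES) +
            1L]
        subsysSingle <- SUBSYSTEM_NAMES[
            (seq_along(singleGenes) - 1L) %% length(SUBSYSTEM_NAMES) + 1L]
        subsys <- c(subsysFam, subsysSingle)
        annTab <- data.frame(
            gene = pathwayGenes, module = MODULE_OF_SUBSYSTEM[subsys],
            subsystem = subsys,
            family = c(famAll, rep("none", length(singleGenes))),
            secretory_client = FALSE, complex_count = NA_integer_,
            stringsAsFactors = FALSE)
    }
    annotation <- if (!is.null(annTab)) PathwayAnnotation(annTab) else NULL

    ptm <- NULL
    if (plan@nSecretome > 0L)
        ptm <- PTMTable(data.frame(
            protein = secGenes,
            n_glyc_sites = st$ng, o_glyc_sites = st$og,
            disulfide_sites = as.integer(st$ds), gpi_sites = st$gpi,
            tm_domains = st$tm, has_signal_peptide = st$hasSP,
            secretomep_score = st$score, localization = st$localization,
            stringsAsFactors = FALSE))

    truthCats <- if (plan@categoryQuota > 0L)
        data.frame(gene = plantGenes,
                   category = rep(catNames, each = plan@categoryQuota),
                   stringsAsFactors = FALSE)
    else data.frame(gene = character(0L), category = character(0L))

    list(primary = primary, validation = validation,
         annotation = annotation, ptm = ptm,
         truth = list(spikes = st$spikes, categories = truthCats,
                      lowGroup = st$lowGroup, enzymeGenes = enzymeGenes,
                      enzymeSlope = plan@enzymeSlope, dsLoads = dsLoads))
}

#' Write a complete fixture bundle to disk
#'
#' Emits every artifact in the dialects the loaders read — the two
#' expression TSVs, the annotation TSV, the UniProt-dialect PTM GFF with
#' its companion score table, the ground truth as YAML — plus a
#' `manifest.tsv` of md5 checksums.
#'
#' @param plan a [SimulationPlan-class].
#' @param outDir output directory (created if missing).
#' @return Invisibly, named character vector of the written paths.
#' @export
emitFixtureBundle <- function(plan, outDir) {
    if (!dir.exists(outDir) &&
        !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
        stop("cannot create output directory: ", outDir)
    sim <- simulateSecData(plan)
    paths <- c(
        expression_primary = file.path(outDir, "expression_primary.tsv"),
        expression_validation = file.path(outDir,
                                          "expression_validation.tsv"),
        annotation = file.path(outDir, "annotation.tsv"),
        ptm_gff = file.path(outDir, "ptm_features.gff"),
        ptm_meta = file.path(outDir, "ptm_meta.tsv"),
        ground_truth = file.path(outDir, "ground_truth.yaml"))
    writeExpression(sim$primary, paths["expression_primary"])
    writeExpression(sim$validation, paths["expression_validation"])
    if (!is.null(sim$annotation))
        writePathwayAnnotation(sim$annotation, paths["annotation"])
    else paths <- paths[names(paths) != "annotation"]
    if (!is.null(sim$ptm)) {
        writePTMAsGFF(sim$ptm, paths["ptm_gff"], paths["ptm_meta"])
    } else paths <- paths[!names(paths) %in% c("ptm_gff", "ptm_meta")]
    yaml::write_yaml(list(
        spikes = sim$truth$spikes, lowGroup = sim$truth$lowGroup,
        enzymeGenes = sim$truth$enzymeGenes,
        enzymeSlope = sim$truth$enzymeSlope,
        categories = sim$truth$categories), paths["ground_truth"])
    manifest <- file.path(outDir, "manifest.tsv")
    sums <- tools::md5sum(unname(paths))
    utils::write.table(
        data.frame(file = basename(names(sums)), md5 = unname(sums)),
        manifest, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(paths, manifest = manifest))
}

## serialize a PTMTable in the UniProt GFF dialect + companion meta TSV
writePTMAsGFF <- function(ptm, gffPath, metaPath) {
    tab <- annotationTable(ptm)
    lines <- c("##gff-version 3")
    for (i in seq_len(nrow(tab))) {
        p <- tab$protein[i]
        mk <- function(type, k, note = ".") {
            if (k <= 0L) return(character(0L))
            sprintf("%s\tUniProtKB\t%s\t%d\t%d\t.\t.\t.\t%s",
                    p, type, 10L * seq_len(k), 10L * seq_len(k) + 5L, note)
        }
        lines <- c(lines,
            if (tab$has_signal_peptide[i])
                sprintf("%s\tUniProtKB\tSignal peptide\t1\t22\t.\t.\t.\t.", p),
            mk("Disulfide bond", tab$disulfide_sites[i]),
            mk("Glycosylation", tab$n_glyc_sites[i],
               "Note=N-linked (GlcNAc...) asparagine"),
            mk("Glycosylation", tab$o_glyc_sites[i],
               "Note=O-linked (GalNAc...) threonine"),
            mk("Lipidation", tab$gpi_sites[i],
               "Note=GPI-anchor amidated serine"),
            mk("Transmembrane", tab$tm_domains[i], "Note=Helical"))
    }
    writeLines(lines, gffPath)
    utils::write.table(
        tab[, c("protein", "secretomep_score", "localization")],
        metaPath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(gffPath)
}
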