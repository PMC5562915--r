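test_that("the same plan and seed reproduce outputs exactly", {
    plan <- tinyPlan(seed = 6L)
    s1 <- simulateSecData(plan)
    s2 <- simulateSecData(plan)
    expect_identical(fpkm(s1$primary), fpkm(s2$primary))
    expect_identical(fpkm(s1$validation), fpkm(s2$validation))
    expect_identical(annotationTable(s1$annotation),
                     annotationTable(s2$annotation))
    expect_identical(s1$truth, s2$truth)
    ## a different seed changes the draw
    s3 <- simulateSecData(tinyPlan(seed = 7L))
    expect_false(identical(fpkm(s1$primary), fpkm(s3$primary)))
})

test_that("the two datasets share structure but not noise", {
    sim <- simulateSecData(SimulationPlan(seed = 23L))
    p <- fpkm(sim$primary); v <- fpkm(sim$validation)
    expect_identical(dimnames(p), dimnames(v))
    expect_false(identical(p, v))
    ## spikes are planted in both datasets
    for (i in seq_len(nrow(sim$truth$spikes))) {
        g <- sim$truth$spikes$gene[i]; t <- sim$truth$spikes$tissue[i]
        expect_gt(p[g, t], stats::median(p[g, ]))
        expect_gt(v[g, t], stats::median(v[g, ]))
    }
})

test_that("ground truth references existing entities", {
    sim <- simulateSecData(SimulationPlan(seed = 2L))
    m <- sim$primary
    expect_true(all(sim$truth$spikes$gene %in% rownames(m)))
    expect_true(all(sim$truth$spikes$tissue %in% tissues(m)))
    expect_true(all(sim$truth$categories$gene %in% rownames(m)))
    expect_true(all(sim$truth$lowGroup %in% tissues(m)))
    expect_true(all(sim$truth$enzymeGenes %in% rownames(m)))
    expect_true(all(sim$truth$spikes$fold > 1))
    ## annotation families all have >= 3 members (spiked plans)
    expect_true(all(lengths(geneFamilies(sim$annotation)) >= 3))
})

test_that("infeasible plans are rejected", {
    expect_error(SimulationPlan(nTissues = 8L),
                 "category plants")
    expect_error(SimulationPlan(spikeFold = 1), "fold")
    expect_error(SimulationPlan(lowGroupSize = 30L), "proper")
    expect_error(SimulationPlan(enzymeSize = 2L, nSecretome = 0L),
                 "secretome")
    expect_error(SimulationPlan(
        families = data.frame(name = "F", size = 2L)), "sizes >= 3")
})

test_that("a planted spike is recovered and consensus-validated", {
    plan <- SimulationPlan(
        seed = 9L, nSpikes = 0L, categoryQuota = 0L, lowGroupSize = 0L,
        enzymeSize = 0L, nSecretome = 0L, nBackground = 0L,
        nPathwaySingletons = 0L,
        spikes = data.frame(gene = "GF05_2", tissue = "tissue_12",
                            fold = 10))
    sim <- simulateSecData(plan)
    cc <- consensusCalls(
        suppressMessages(detectExtremeGenes(sim$primary, sim$annotation)),
        suppressMessages(detectExtremeGenes(sim$validation,
                                            sim$annotation)))
    hit <- cc[cc$gene == "GF05_2" & cc$tissue == "tissue_12", ]
    expect_identical(nrow(hit), 1L)
    expect_true(hit$validated)
})

test_that("null Grubbs calls stay within the family-wise bound in the
           near-normal regime", {
    ## With modest log-scale noise the family shares are close enough to
    ## normal for the nominal level to hold; at realistic noise the
    ## per-dataset test is anti-conservative (lognormal skew) and the
    ## cross-dataset consensus is the operative control (see the extreme
    ## detection tests and the methods vignette).
    alpha <- 0.05
    totGenes <- 0L; totCalls <- 0L
    ps <- c()
    for (s in 1:50) {
        plan <- SimulationPlan(
            seed = 500L + s, nSpikes = 0L, lowGroupSize = 0L,
            categoryQuota = 0L, enzymeSize = 0L, nSecretome = 0L,
            nBackground = 0L, nPathwaySingletons = 0L,
            tissueSd = 0.03, replicateNoiseSd = 0.04)
        sim <- simulateSecData(plan)
        calls <- suppressMessages(detectExtremeGenes(sim$primary,
                                                     sim$annotation,
                                                     alpha = alpha))
        totCalls <- totCalls + nrow(calls)
        totGenes <- totGenes + nrow(sim$primary)
        if (s <= 25L) {
            fams <- geneFamilies(sim$annotation)
            for (f in names(fams)) {
                sh <- familyShare(sim$primary, fams[[f]])
                ps <- c(ps, apply(sh, 1L, function(x) grubbsTest(x)@p))
            }
        }
    }
    ## per-family false-call rate <= alpha * (family size) is equivalent
    ## to a per-gene rate <= alpha
    expect_lte(totCalls / totGenes, alpha)
    ## p-values are calibrated in the calling regime (the two-sided
    ## union-bound p is conservative near 1 by construction)
    for (u in c(0.05, 0.1, 0.2))
        expect_lt(abs(mean(ps <= u) - u), 0.04)
})

test_that("fixture bundles round-trip and their checksums verify", {
    dir <- withr::local_tempdir()
    plan <- tinyPlan(seed = 12L)
    paths <- emitFixtureBundle(plan, dir)
    sim <- simulateSecData(plan)

    m <- loadExpression(paths[["expression_primary"]], "primary")
    expect_equal(fpkm(m), fpkm(sim$primary), tolerance = 1e-12)
    ann <- loadPathwayAnnotation(paths[["annotation"]])
    expect_identical(geneFamilies(ann), geneFamilies(sim$annotation))
    ptm <- parseUniprotGFF(paths[["ptm_gff"]],
                           metaPath = paths[["ptm_meta"]])
    inMem <- annotationTable(sim$ptm)
    onDisk <- annotationTable(ptm)
    i <- match(inMem$protein, onDisk$protein)
    p <- !is.na(i)
    expect_identical(onDisk$disulfide_sites[i[p]],
                     inMem$disulfide_sites[p])
    expect_identical(onDisk$has_signal_peptide[i[p]],
                     inMem$has_signal_peptide[p])
    expect_equal(onDisk$secretomep_score[i[p]],
                 inMem$secretomep_score[p])
    ## proteins without any feature have no GFF record at all
    none <- inMem[is.na(i), ]
    expect_true(all(!none$has_signal_peptide & none$disulfide_sites == 0 &
                    none$n_glyc_sites == 0 & none$o_glyc_sites == 0 &
                    none$gpi_sites == 0 & none$tm_domains == 0))

    man <- utils::read.delim(paths[["manifest"]])
    sums <- tools::md5sum(file.path(dir, man$file))
    expect_identical(unname(sums), man$md5)

    ## identical plan -> byte-identical bundle
    dir2 <- withr::local_tempdir()
    paths2 <- emitFixtureBundle(plan, dir2)
    for (nm in setdiff(names(paths), "manifest"))
        expect_identical(readLines(paths[[nm]]), readLines(paths2[[nm]]))
})
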