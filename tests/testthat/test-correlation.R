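test_that("perfectly related tissue profiles give rho = +/-1", {
    ## identical profiles
    m <- toyFPKM(cbind(t1 = c(1, 5, 9), t2 = c(1, 5, 9)))
    rho <- crossTissueCorrelation(m, rownames(m))
    expect_equal(rho["t1", "t2"], 1)

    ## anti-linear on the raw scale
    a <- c(1, 4, 9)
    m2 <- toyFPKM(cbind(t1 = a, t2 = -a + 10))
    rho2 <- crossTissueCorrelation(m2, rownames(m2), logTransform = FALSE)
    expect_equal(rho2["t1", "t2"], -1)

    ## proportional profiles, raw scale
    m3 <- toyFPKM(cbind(A = c(1, 2, 3), B = c(2, 4, 6)))
    rho3 <- crossTissueCorrelation(m3, rownames(m3), logTransform = FALSE)
    expect_equal(rho3["A", "B"], 1)
})

test_that("correlation matrix is symmetric with unit diagonal", {
    sim <- simulateSecData(tinyPlan(seed = 2L))
    rho <- crossTissueCorrelation(sim$primary, genes(sim$annotation))
    expect_lt(max(abs(rho - t(rho))), 1e-12)
    expect_identical(unname(diag(rho)), rep(1, ncol(rho)))
    expect_true(all(rho >= -1 - 1e-12 & rho <= 1 + 1e-12))
    expect_error(crossTissueCorrelation(sim$primary, "absent-gene"),
                 "at least 2 genes")
})

test_that("zero-variance tissues yield flagged missing entries", {
    m <- toyFPKM(cbind(t1 = c(1, 5, 9), t2 = c(2, 2, 2), t3 = c(3, 1, 7)))
    expect_message(rho <- crossTissueCorrelation(m, rownames(m)),
                   "zero-variance")
    expect_true(is.na(rho["t1", "t2"]))
    expect_false(is.na(rho["t1", "t3"]))
    expect_error(clusterTissues(rho), "missing")
})

test_that("clustering recovers a planted block split", {
    tn <- c("a", "b", "c", "d", "e")
    rho <- matrix(0.3, 5, 5, dimnames = list(tn, tn))
    rho[1:2, 1:2] <- 0.95
    rho[3:5, 3:5] <- 0.95
    diag(rho) <- 1
    cl <- clusterTissues(rho)
    expect_identical(cl$groups[["a"]], cl$groups[["b"]])
    expect_identical(cl$groups[["c"]], cl$groups[["d"]])
    expect_identical(cl$groups[["d"]], cl$groups[["e"]])
    expect_false(cl$groups[["a"]] == cl$groups[["c"]])
    expect_match(cl$newick, "^\\(")

    ## permuting tissues leaves the partition identical (labels may swap)
    perm <- c(3, 1, 5, 2, 4)
    cl2 <- clusterTissues(rho[perm, perm])
    samePartition <- function(a, b)
        identical(outer(a, a, "=="), outer(b[names(a)], b[names(a)], "=="))
    expect_true(samePartition(cl$groups, cl2$groups))

    ones <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
    expect_warning(cld <- clusterTissues(ones), "arbitrary")
    expect_true(cld$degenerate)
})

test_that("permutation test is deterministic, add-one bounded, and calibrated", {
    sim <- simulateSecData(SimulationPlan(seed = 1L))
    pg <- genes(sim$annotation)
    pt1 <- lowGroupPermutationTest(sim$primary, pg, sim$truth$lowGroup,
                                   nPerm = 199L, seed = 9L)
    pt2 <- lowGroupPermutationTest(sim$primary, pg, sim$truth$lowGroup,
                                   nPerm = 199L, seed = 9L)
    expect_identical(pt1$p, pt2$p)
    expect_identical(pt1$null, pt2$null)
    expect_gt(pt1$p, 0)
    expect_lte(pt1$p, 1)

    ## planted low-correlation group is significant
    pt3 <- lowGroupPermutationTest(sim$primary, pg, sim$truth$lowGroup,
                                   nPerm = 999L, seed = 1L)
    expect_lte(pt3$p, 0.05)

    ## the full gene set is its own null: uninformative, never 0
    ptAll <- lowGroupPermutationTest(sim$primary, rownames(sim$primary),
                                     sim$truth$lowGroup, nPerm = 199L,
                                     seed = 2L)
    expect_gte(ptAll$p, 0.5)

    expect_error(lowGroupPermutationTest(sim$primary, pg,
                                         tissues(sim$primary)),
                 "proper subset")
    expect_warning(lowGroupPermutationTest(sim$primary, pg,
                                           sim$truth$lowGroup,
                                           nPerm = 50L, seed = 1L),
                   "nPerm")
})

test_that("family profiles handle proportional members and small families", {
    ## log10(FPKM + 1) profiles that are exactly additive in member and
    ## tissue effects correlate perfectly for every tissue pair
    L <- outer(c(f1 = 0, f2 = 1, f3 = 0.5), c(t1 = 1, t2 = 2, t3 = 3,
                                              t4 = 2.2), "+")
    prof <- 10^L - 1
    m <- toyFPKM(rbind(prof, other = c(1, 1, 1, 1)))
    ann <- toyAnnotation(rownames(m), c("F", "F", "F", "none"))
    res <- familyCorrelationProfiles(m, ann)
    expect_equal(res$rho, rep(1, 6))
    expect_identical(nrow(res), 6L)

    ## reference-tissue mode
    res2 <- familyCorrelationProfiles(m, ann, referenceTissue = "t2")
    expect_identical(nrow(res2), 3L)
    expect_true(all(res2$tissue1 == "t2"))

    ## families below the minimum size are skipped
    ann2 <- toyAnnotation(rownames(m), c("F", "F", "none", "none"))
    expect_message(res3 <- familyCorrelationProfiles(m, ann2), "skipping")
    expect_identical(nrow(res3), 0L)
})

test_that("a spiking member depresses its family's correlations", {
    ## members share a tissue profile shape (scaled per member, light
    ## noise), so every tissue pair correlates near 1; one member then
    ## spikes only in tissue t1
    withr::with_seed(21, {
        tissueProfile <- exp(stats::rnorm(8, 1, 0.5))
        memberScale <- exp(stats::rnorm(5, 0, 0.6))
        base <- outer(memberScale, tissueProfile) *
            matrix(exp(stats::rnorm(40, 0, 0.05)), 5, 8)
        dimnames(base) <- list(sprintf("f%d", 1:5), sprintf("t%d", 1:8))
        spiked <- base
        spiked["f3", "t1"] <- spiked["f3", "t1"] * 15
        ann <- toyAnnotation(rownames(base), rep("F", 5))
        withSpike <- familyCorrelationProfiles(toyFPKM(spiked), ann)
        ## removing the spiked member restores the family's coherence
        mClean <- toyFPKM(spiked[rownames(spiked) != "f3", ])
        annClean <- toyAnnotation(rownames(mClean), rep("F", 4))
        noSpike <- familyCorrelationProfiles(mClean, annClean)
        involvesP <- withSpike$tissue1 == "t1" | withSpike$tissue2 == "t1"
        expect_true(all(withSpike$rho[involvesP] <
                        noSpike$rho[involvesP]))
        expect_gt(min(noSpike$rho), 0.9)
    })
})
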