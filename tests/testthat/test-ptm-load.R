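mkPTM <- function(...) PTMTable(data.frame(..., stringsAsFactors = FALSE))

test_that("secretome filters follow the signal-peptide / score rules", {
    ptm <- mkPTM(protein = c("sp", "unconv", "neither"),
                 has_signal_peptide = c(TRUE, FALSE, FALSE),
                 secretomep_score = c(NA, 0.7, 0.2),
                 disulfide_sites = c(2L, 1L, 0L))
    sec <- defineSecretome(ptm)
    expect_identical(genes(sec), "sp")
    expect_identical(sec@excluded, "unconv")
    expect_identical(sec@dropped, "neither")

    allSP <- mkPTM(protein = c("a", "b"),
                   has_signal_peptide = c(TRUE, TRUE))
    expect_setequal(genes(defineSecretome(allSP)), c("a", "b"))

    none <- mkPTM(protein = "x", has_signal_peptide = FALSE,
                  secretomep_score = 0.9)
    expect_error(defineSecretome(none), "empty")
})

test_that("category restriction narrows the analysis set as planned", {
    ptm <- mkPTM(protein = c("a", "b", "c"),
                 has_signal_peptide = c(TRUE, TRUE, TRUE))
    cats <- data.frame(gene = c("a", "b", "c"),
                       category = c("TissueEnriched", "ExpressedInAll",
                                    "TissueEnhanced"))
    sec <- defineSecretome(ptm, categories = cats)
    expect_setequal(genes(sec), c("a", "c"))
    secE <- defineSecretome(ptm, categories = cats,
                            restrictTo = "TissueEnriched")
    expect_identical(genes(secE), "a")
})

test_that("DS_e matches hand computations and flags zero loads", {
    ptm <- mkPTM(protein = c("g1", "g2"),
                 has_signal_peptide = c(TRUE, TRUE),
                 disulfide_sites = c(10L, 0L))
    sec <- defineSecretome(ptm)
    ## one gene, fpkm 10, ds 10 -> log10(100) = 2
    m1 <- toyFPKM(matrix(c(10, 3), 2, 1), genes = c("g1", "g2"),
                  tissues = "t1")
    l1 <- disulfideEnrichment(m1, sec, ptm)
    expect_equal(l1$ds_e, 2)

    ## (fpkm 5, ds 2) + (fpkm 10, ds 0) -> log10(10) = 1
    ptm2 <- mkPTM(protein = c("g1", "g2"),
                  has_signal_peptide = c(TRUE, TRUE),
                  disulfide_sites = c(2L, 0L))
    m2 <- toyFPKM(matrix(c(5, 10), 2, 1), genes = c("g1", "g2"),
                  tissues = "t1")
    l2 <- disulfideEnrichment(m2, defineSecretome(ptm2), ptm2)
    expect_equal(l2$ds_e, 1)
    expect_identical(l2$n_genes, 1L)

    ## all ds = 0 -> undefined
    ptm3 <- mkPTM(protein = c("g1", "g2"),
                  has_signal_peptide = c(TRUE, TRUE),
                  disulfide_sites = c(0L, 0L))
    l3 <- disulfideEnrichment(m2, defineSecretome(ptm3), ptm3)
    expect_true(all(l3$undefined))
    expect_true(all(is.na(l3$ds_e)))

    ## secretome genes missing from the PTM table count as ds = 0, flagged
    ptm4 <- mkPTM(protein = "g1", has_signal_peptide = TRUE,
                  disulfide_sites = 2L)
    sec4 <- new("SecretomeSet", genes = c("g1", "g2"),
                excluded = character(0), dropped = character(0),
                localization = c(g1 = "Secreted", g2 = "Secreted"))
    expect_message(l4 <- disulfideEnrichment(m2, sec4, ptm4),
                   "without PTM annotation")
    expect_identical(attr(l4, "nUnannotated"), 1L)
    expect_equal(l4$ds_e, 1)  # only g1 contributes
})

test_that("DS_e is monotone and additive over disjoint subsets", {
    withr::with_seed(13, {
        n <- 6
        ptm <- mkPTM(protein = sprintf("g%d", 1:n),
                     has_signal_peptide = TRUE,
                     disulfide_sites = stats::rpois(n, 5) + 1L)
        v <- matrix(stats::rlnorm(n * 4, 1, 1), n, 4)
        m <- toyFPKM(v, genes = sprintf("g%d", 1:n))
        sec <- defineSecretome(ptm)
        l <- disulfideEnrichment(m, sec, ptm)

        ## raising one gene's fpkm raises every tissue load it touches
        v2 <- v; v2[3, ] <- v2[3, ] * 5
        l2 <- disulfideEnrichment(toyFPKM(v2, genes = sprintf("g%d", 1:n)),
                                  sec, ptm)
        expect_true(all(l2$ds_e >= l$ds_e))

        ## merging disjoint subsets: ds_e = log10(10^a + 10^b)
        secA <- new("SecretomeSet", genes = sprintf("g%d", 1:3),
                    excluded = character(0), dropped = character(0),
                    localization = character(0))
        secB <- new("SecretomeSet", genes = sprintf("g%d", 4:6),
                    excluded = character(0), dropped = character(0),
                    localization = character(0))
        a <- disulfideEnrichment(m, secA, ptm)$ds_e
        b <- disulfideEnrichment(m, secB, ptm)$ds_e
        expect_equal(l$ds_e, log10(10^a + 10^b))
    })
})

test_that("planted enzyme slope is recovered by the regression", {
    sim <- simulateSecData(SimulationPlan(seed = 17L))
    sec <- defineSecretome(sim$ptm)
    loads <- suppressMessages(disulfideEnrichment(sim$primary, sec,
                                                  sim$ptm))
    assoc <- associateFamilyWithLoad(sim$primary, sim$truth$enzymeGenes,
                                     loads)
    expect_identical(nrow(assoc), length(sim$truth$enzymeGenes))
    relErr <- abs(assoc$slope - sim$truth$enzymeSlope) /
        sim$truth$enzymeSlope
    expect_lt(stats::median(relErr), 0.1)
    expect_true(all(assoc$p_value < 0.001))
    expect_true(all(assoc$slope_ci_lo < assoc$slope &
                    assoc$slope < assoc$slope_ci_hi))
})

test_that("a load-independent gene shows no systematic association", {
    ps <- vapply(1:25, function(s) {
        sim <- simulateSecData(SimulationPlan(
            seed = 400L + s, categoryQuota = 0L, nSpikes = 0L,
            lowGroupSize = 0L))
        sec <- defineSecretome(sim$ptm)
        loads <- suppressMessages(
            disulfideEnrichment(sim$primary, sec, sim$ptm))
        ## background genes are independent of the disulfide load
        a <- associateFamilyWithLoad(sim$primary, "BG0001", loads)
        a$p_value
    }, 0)
    expect_gt(stats::median(ps), 0.1)
    expect_lte(mean(ps < 0.05), 0.2)
})

test_that("regression preconditions are enforced", {
    ptm <- mkPTM(protein = "g1", has_signal_peptide = TRUE,
                 disulfide_sites = 3L)
    sec <- defineSecretome(ptm)
    m <- toyFPKM(matrix(c(1, 2), 1, 2), genes = "g1")
    loads <- disulfideEnrichment(m, sec, ptm)
    expect_error(associateFamilyWithLoad(m, "g1", loads), "at least 3")

    m3 <- toyFPKM(matrix(c(5, 5, 5), 1, 3), genes = "g1")
    loads3 <- disulfideEnrichment(m3, sec, ptm)
    expect_error(associateFamilyWithLoad(m3, "g1", loads3), "degenerate")
})

test_that("tercile binning matches a brute-force oracle", {
    counts <- c(0L, 1L, 5L, 50L)
    ## oracle: terciles of the nonzero values
    nz <- counts[counts > 0]
    cuts <- stats::quantile(nz, c(1, 2) / 3)
    oracle <- ifelse(counts == 0, "none",
              ifelse(counts <= cuts[1], "low",
              ifelse(counts <= cuts[2], "medium", "high")))
    ptm <- mkPTM(protein = sprintf("p%d", 1:4),
                 has_signal_peptide = TRUE,
                 n_glyc_sites = counts)
    sec <- defineSecretome(ptm)
    tab <- ptmAnnotationMatrix(sec, ptm)
    expect_identical(as.character(tab$n_glyc_bin[match(sprintf("p%d", 1:4),
                                                       tab$gene)]),
                     oracle)
    expect_identical(as.character(unique(tab$gpi_bin)), "none")

    ## gene order does not change the bins
    ptm2 <- mkPTM(protein = sprintf("p%d", 4:1),
                  has_signal_peptide = TRUE,
                  n_glyc_sites = rev(counts))
    tab2 <- ptmAnnotationMatrix(defineSecretome(ptm2), ptm2)
    expect_identical(
        as.character(tab$n_glyc_bin[match(sprintf("p%d", 1:4), tab$gene)]),
        as.character(tab2$n_glyc_bin[match(sprintf("p%d", 1:4),
                                           tab2$gene)]))
})

test_that("excluding unconventional proteins never raises the load", {
    ptm <- mkPTM(protein = c("sp1", "sp2", "u1"),
                 has_signal_peptide = c(TRUE, TRUE, FALSE),
                 secretomep_score = c(NA, NA, 0.8),
                 disulfide_sites = c(2L, 1L, 6L))
    m <- toyFPKM(matrix(c(4, 2, 9, 1, 1, 1), 3, 2),
                 genes = c("sp1", "sp2", "u1"))
    sec <- defineSecretome(ptm)
    with <- new("SecretomeSet", genes = c(genes(sec), "u1"),
                excluded = character(0), dropped = character(0),
                localization = character(0))
    expect_true(all(disulfideEnrichment(m, sec, ptm)$ds_e <=
                    disulfideEnrichment(m, with, ptm)$ds_e))
})
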