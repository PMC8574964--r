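## Matched-pair fixture: nPairs omentum/ascites TU pairs with given TPM rows.
pairSE <- function(A, B) {
    np <- ncol(A)
    m <- matrix(0, nrow(A), 2L * np)
    ids <- character(2L * np)
    for (p in seq_len(np)) {
        m[, 2L * p - 1L] <- A[, p]; m[, 2L * p] <- B[, p]
        ids[c(2L * p - 1L, 2L * p)] <- sprintf(c("om_P%02d", "as_P%02d"), p)
    }
    dimnames(m) <- list(rownames(A), ids)
    makeSE(m, "TU",
           compartments = rep(c("omentum", "ascites"), np),
           patients = rep(sprintf("P%02d", seq_len(np)), each = 2L))
}

test_that("paired t-test matches the closed form and stats::t.test", {
    ## paired log2 differences {1, 2, 3}: t = 2 / (1/sqrt(3)) = 3.4641
    B <- matrix(1, 1, 3, dimnames = list("g", NULL))
    A <- matrix(2^(1:3 + 1) - 1, 1, 3, dimnames = list("g", NULL))
    x <- pairSE(A, B)
    pairs <- matchedPairs(x, "TU")
    expect_identical(nrow(pairs), 3L)
    de <- pairedDE(x, pairs)
    tref <- stats::t.test(log2(A + 1) - log2(B + 1))
    expect_equal(de$p, tref$p.value, tolerance = 1e-12)
    expect_equal(de$p, 2 * pt(-2 / (1 / sqrt(3)), df = 2), tolerance = 1e-12)
    expect_false(de$called)   # p ~ 0.074 > 0.05

    ## identical values across pairs: zero variance, p = 1, not called
    x0 <- pairSE(matrix(8, 1, 3, dimnames = list("g", NULL)),
                 matrix(8, 1, 3, dimnames = list("g", NULL)))
    de0 <- pairedDE(x0, matchedPairs(x0, "TU"))
    expect_equal(de0$p, 1)
    expect_true(de0$zero_variance)
    expect_false(de0$called)

    ## fewer than 3 pairs is a hard error
    x2 <- pairSE(A[, 1:2, drop = FALSE], B[, 1:2, drop = FALSE])
    expect_error(pairedDE(x2, matchedPairs(x2, "TU")), "3 matched pairs")
})

test_that("swapping conditions mirrors directions and preserves the called set", {
    sim <- generateMatchedPairs(testSimConfig(seed = 4, nPairGenes = 300L,
                                              nDEGenes = 30L))
    de <- pairedDE(sim$se, sim$pairs)
    swapped <- sim$pairs
    names(swapped)[2:3] <- c("sample_B", "sample_A")
    de2 <- pairedDE(sim$se, swapped[, c("patient_id", "sample_A",
                                        "sample_B")])
    expect_identical(de$called, de2$called)
    up <- de$called & de$direction == "up"
    expect_identical(de2$direction[up], rep("down", sum(up)))
    expect_equal(de$p, de2$p, tolerance = 1e-12)
})

test_that("planted fold changes are recovered with high sensitivity", {
    sim <- generateMatchedPairs(testSimConfig(seed = 12, nPairGenes = 1000L,
                                              nDEGenes = 200L, deFold = 8))
    de <- pairedDE(sim$se, sim$pairs)
    planted <- sim$truth$gene[sim$truth$fold != 1]
    sens <- mean(de$called[de$gene %in% planted])
    expect_gte(sens, 0.9)
    ## directions agree with the planted truth among correct calls
    hit <- de$gene %in% planted & de$called
    expect_identical(de$direction[hit],
                     sim$truth$direction[match(de$gene[hit],
                                               sim$truth$gene)])
})

test_that("BH adjustment matches hand computation and validates input", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.3), 0.3)                 # m = 1
    expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5)) # all equal
    expect_error(bhAdjust(c(0.5, 0)), "\\(0, 1\\]")
    expect_error(bhAdjust(c(0.5, 1.2)), "\\(0, 1\\]")

    ## agreement with an independent brute-force step-up implementation
    set.seed(2)
    grid <- seq(0.01, 1, by = 0.01)
    for (i in 1:200) {
        p <- sample(grid, sample(1:6, 1), replace = TRUE)
        expect_equal(bhAdjust(p), bruteForceBH(p), tolerance = 1e-12)
    }
})

test_that("matched profile correlation behaves under monotone maps and reversal", {
    A <- matrix(1:10, 10, 3, dimnames = list(sprintf("g%02d", 1:10), NULL))
    xid <- pairSE(A, A)
    pid <- matchedPairs(xid, "TU")
    expect_equal(matchedCorrelation(xid, pid, "spearman"), 1)
    expect_equal(matchedCorrelation(xid, pid, "pearson"), 1)

    ## strictly monotone transform: Spearman 1, Pearson below 1
    xmono <- pairSE(A^3, A)
    expect_equal(matchedCorrelation(xmono, pid, "spearman"), 1)
    expect_lt(matchedCorrelation(xmono, pid, "pearson"), 1)

    ## rank reversal
    xrev <- pairSE(A, 11 - A)
    expect_equal(matchedCorrelation(xrev, pid, "spearman"), -1)
})

test_that("the dual-significance survival filter keeps and labels the published genes", {
    tab <- readSurvivalStats(system.file("extdata",
                                         "stroma_survival_stats.tsv",
                                         package = "TMEnet"))
    expect_identical(nrow(tab), 32L)
    out <- survivalFilter(tab)
    expect_identical(nrow(out), 32L)
    expect_identical(sum(out$direction == "short survival"), 31L)
    expect_identical(out$direction[out$gene == "BDNF"], "long survival")
    expect_identical(out$direction[out$gene == "PDGFD"], "short survival")

    ## non-significant rows are dropped
    extra <- rbind(tab, data.frame(gene = "X", rfs_p = 0.2, rfs_hr = 1.4,
                                   os_z = 3.0, cell_types = "CAF"))
    expect_false("X" %in% survivalFilter(extra)$gene)
    extra2 <- rbind(tab, data.frame(gene = "Y", rfs_p = 0.01, rfs_hr = 1.4,
                                    os_z = 1.5, cell_types = "CAF"))
    expect_false("Y" %in% survivalFilter(extra2)$gene)
})
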