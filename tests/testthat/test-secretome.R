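lfqRow <- function(protein, sample, timepoint, lfq, det = TRUE) {
    data.frame(protein = protein, sample = sample, timepoint = timepoint,
               lfq = lfq, peptide_detected = det)
}

test_that("secretion signal is the late-minus-baseline difference", {
    expect_equal(secretionSignal(5, 7), 2)
    expect_equal(secretionSignal(6, 6), 0)
    expect_equal(secretionSignal(NA, 6), 6)          # missing t0 = absence
    expect_true(is.na(secretionSignal(NA, 6, missingT0 = "drop")))
})

test_that("secretome calls require a detected peptide and a strictly higher late median", {
    tab <- rbind(
        lfqRow("P1", c("a", "b"), "t0", c(5, 5)),
        lfqRow("P1", c("a", "b"), "t_late", c(7, 7)),
        lfqRow("P2", c("a", "b"), "t0", c(6, 6)),
        lfqRow("P2", c("a", "b"), "t_late", c(6, 6)),
        lfqRow("P3", c("a", "b"), "t0", c(2, 2), det = FALSE),
        lfqRow("P3", c("a", "b"), "t_late", c(9, 9), det = FALSE))
    calls <- callSecretome(tab)
    get <- function(p) calls$in_secretome[calls$protein == p]
    expect_true(get("P1"))    # higher late median, detected
    expect_false(get("P2"))   # equal medians: strict comparison
    expect_false(get("P3"))   # no peptide anywhere
    expect_equal(calls$secretion_signal[calls$protein == "P1"], 2)

    ## invariance under a strictly increasing transform of all LFQ values
    tab2 <- tab; tab2$lfq <- exp(tab2$lfq)
    expect_identical(callSecretome(tab2)$in_secretome, calls$in_secretome)
})

test_that("detection rates per TPM bin hit the saturation and floor cases", {
    tpmMed <- c(a = 0.5, b = 5, c = 50, d = 500)
    allIn <- data.frame(protein = names(tpmMed), in_secretome = TRUE,
                        secretion_signal = 1)
    edges <- c(0, 1, 10, 100, 1000)
    r <- detectionRateByExpression(tpmMed, allIn, edges)
    expect_equal(r$fraction, rep(1, 4))
    noneIn <- transform(allIn, in_secretome = FALSE)
    expect_equal(detectionRateByExpression(tpmMed, noneIn, edges)$fraction,
                 rep(0, 4))
    ## empty bin reported as missing
    r2 <- detectionRateByExpression(tpmMed[c("a", "d")], allIn,
                                    c(0, 1, 10, 1000))
    expect_true(is.na(r2$fraction[2]))
    ## bins must cover the range
    expect_error(detectionRateByExpression(tpmMed, allIn, c(0, 1, 10)),
                 "cover")
})

test_that("logistic detection yields monotone per-bin rates and truth-consistent counts", {
    cfg <- testSimConfig(seed = 19, nGenes = 3000L,
                         nSecretomeProteins = 1500L, lfqNoiseSigma = 0)
    pure <- generatePureProfiles(cfg)
    lrs <- generateLigandReceptorSecretome(cfg, pure)
    calls <- callSecretome(lrs$lfq)

    ## calls match the generator's planted detection truth exactly
    truth <- lrs$truth$detected
    expect_identical(stats::setNames(calls$in_secretome, calls$protein)[
        names(truth)], truth)

    tpmMed <- pure$profiles[names(truth), lrs$truth$secretomeCellType]
    edges <- c(0, 1, 5, 20, 80, 320, max(tpmMed) + 1)
    r <- detectionRateByExpression(tpmMed, calls, edges)
    ok <- !is.na(r$fraction)
    fr <- r$fraction[ok]; n <- r$n[ok]
    ## non-decreasing within binomial 95% slack
    slack <- 1.96 * sqrt(pmax(fr * (1 - fr), 0.25 / n) / n)
    expect_true(all(diff(fr) >= -(slack[-length(slack)] + slack[-1L])))
})

test_that("RNA-protein correlation is 1 for monotone LFQ and near 0 when permuted", {
    cfg <- testSimConfig(seed = 29, nGenes = 3000L,
                         nSecretomeProteins = 500L, lfqNoiseSigma = 0)
    pure <- generatePureProfiles(cfg)
    lrs <- generateLigandReceptorSecretome(cfg, pure)
    calls <- callSecretome(lrs$lfq)
    tpmMed <- pure$profiles[, lrs$truth$secretomeCellType]
    late <- lrs$lfq[lrs$lfq$timepoint == "t_late", ]
    lfqMed <- tapply(late$lfq, late$protein, median)

    ## noise-free affine-log LFQ is a strictly monotone map of TPM
    rho <- rnaProteinCorrelation(tpmMed, lfqMed, "spearman", calls)
    expect_equal(rho, 1)

    ## permuting the LFQ values destroys the association
    set.seed(1)
    inSec <- calls$protein[calls$in_secretome]
    perm <- stats::setNames(sample(lfqMed[inSec]), inSec)
    expect_lt(abs(rnaProteinCorrelation(tpmMed, perm, "spearman", calls)),
              0.15)

    ## ties are handled by average ranks
    tied <- c(g1 = 5, g2 = 5, g3 = 7)
    lq <- c(g1 = 1, g2 = 2, g3 = 3)
    expect_true(is.finite(rnaProteinCorrelation(
        tied, lq, "spearman",
        data.frame(protein = names(lq), in_secretome = TRUE))))
    expect_error(rnaProteinCorrelation(tied[1:2], lq[1:2], "spearman"),
                 "fewer than 3")
})

test_that("secretome/transcriptome overlap counts match the generator truth", {
    cfg <- testSimConfig(seed = 37, lfqNoiseSigma = 0)
    pure <- generatePureProfiles(cfg)
    lrs <- generateLigandReceptorSecretome(cfg, pure)
    calls <- callSecretome(lrs$lfq)
    tpmMed <- pure$profiles[, lrs$truth$secretomeCellType]

    secr <- calls$protein[calls$in_secretome]
    transcr <- names(tpmMed)[tpmMed > 0.3]
    overlap <- intersect(secr, transcr)
    secrOnly <- setdiff(secr, transcr)
    expect_identical(length(overlap) + length(secrOnly), length(secr))
    expect_identical(sort(secr), sort(names(which(lrs$truth$detected))))
})
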