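## Build a tiny two-type world with ideal markers: target TU is zero at the
## contaminant's markers, contaminant TAM expresses them highly.
idealWorld <- function() {
    genes <- c(sprintf("mk%02d", 1:25), sprintf("bg%02d", 1:25))
    tu <- c(rep(0, 25), rep(1000, 25))
    tam <- c(rep(1000, 25), rep(1000, 25))
    names(tu) <- names(tam) <- genes
    ms <- TMEnet:::MarkerSet("TU", "TAM", genes[1:25], rep(100, 25))
    list(genes = genes, tu = tu, tam = tam, ms = ms)
}

test_that("reference choice minimizes contaminating marker RNA and honours pins", {
    w <- idealWorld()
    mix <- 0.9 * w$tu + 0.1 * w$tam
    m <- cbind(TUpure = w$tu, TUmix = mix, TAM1 = w$tam)
    rownames(m) <- w$genes
    x <- makeSE(m, c("TU", "TU", "TAM"))
    expect_identical(chooseReferenceSample(x, "TU", list(w$ms)), "TUpure")
    ## single sample of a type is its own reference
    expect_identical(chooseReferenceSample(x, "TAM", list()), "TAM1")
    ## a pinned is_reference flag overrides the automatic choice
    x2 <- makeSE(m, c("TU", "TU", "TAM"), isRef = c(FALSE, TRUE, FALSE))
    expect_identical(chooseReferenceSample(x2, "TU", list(w$ms)), "TUmix")
})

test_that("contamination estimation recovers mixing fractions on ideal markers", {
    w <- idealWorld()
    ## the reference itself estimates at zero (floored to floor_percent)
    est0 <- estimateContamination(w$tu, w$tu, w$tam, w$ms, floorPercent = 0)
    expect_equal(as.numeric(est0), 0)
    expect_false(attr(est0, "floored"))

    ## 10% mixture: each marker gives 100 * (0.1 * 1000) / 1000 = 10
    mix <- 0.9 * w$tu + 0.1 * w$tam
    est <- estimateContamination(mix, w$tu, w$tam, w$ms)
    expect_equal(as.numeric(est), 10)

    ## the floor binds when the estimate is below it
    estF <- estimateContamination(w$tu, w$tu, w$tam, w$ms, floorPercent = 2)
    expect_equal(as.numeric(estF), 2)
    expect_true(attr(estF, "floored"))

    ## monotone in the true fraction (noise-free)
    fr <- c(0.01, 0.03, 0.07, 0.15, 0.3)
    ests <- vapply(fr, function(f) as.numeric(estimateContamination(
        (1 - f) * w$tu + f * w$tam, w$tu, w$tam, w$ms)), numeric(1))
    expect_false(is.unsorted(ests))
    expect_equal(ests, fr * 100)

    ## zero contaminant reference at a marker drops it with a warning
    tam0 <- w$tam; tam0[1L] <- 0
    expect_warning(estimateContamination(mix, w$tu, tam0, w$ms), "dropped")
})

test_that("noisy marker-based estimates stay within one percentage point", {
    set.seed(101)
    w <- idealWorld()
    trueFrac <- 0.05
    hits <- vapply(seq_len(200), function(i) {
        noise <- function(v) v * exp(rnorm(length(v), 0, 0.2))
        s <- noise((1 - trueFrac) * w$tu + trueFrac * w$tam)
        ## multiplicative noise keeps the target reference at 0 on markers
        est <- as.numeric(estimateContamination(s, noise(w$tu),
                                                noise(w$tam), w$ms))
        abs(est - 5) <= 1
    }, logical(1))
    expect_gte(mean(hits), 0.95)
})

test_that("exclusion thresholds partition samples per cell type", {
    est <- data.frame(
        sample_id = c("tu1", "adi1", "adi1", "caf1"),
        cell_type = c("TU", "ADI", "ADI", "CAF"),
        contaminant = c("TAM", "TU", "TAM", "TU"),
        estimated_percent = c(4.0, 5.9, 5.9, 50),
        floored = FALSE)
    ct <- applyExclusion(TMEnet:::ContaminationTable(est))
    ## TU at exactly 4.0% is excluded (>=); ADI below 6% is kept; CAF has
    ## no default threshold
    expect_identical(excludedSamples(ct), "tu1")

    cfgCAF <- adjustmentConfig(exclusionThreshold = c(TU = 4, CAF = 10))
    expect_setequal(excludedSamples(applyExclusion(
        TMEnet:::ContaminationTable(est), cfgCAF)), c("tu1", "caf1"))
})

test_that("linear unmixing inverts single-contaminant mixtures exactly", {
    ## worked example: (90 - 0.1 * 500) / 0.9
    col <- c(g1 = 90, g2 = 10)
    prof <- list(TAM = c(g1 = 500, g2 = 500))
    out <- adjustSample(col, c(TAM = 0.1), prof)
    expect_equal(unname(out["g1"]), 40 / 0.9, tolerance = 1e-12)
    expect_equal(unname(out["g2"]), 0)   # negative result clamped

    ## frac = 0 is the identity
    expect_identical(adjustSample(col, c(TAM = 0), prof), col)
    ## frac >= 1 is a hard error
    expect_error(adjustSample(col, c(TAM = 1), prof), ">= 1")

    ## inversion property over random profiles
    set.seed(5)
    for (i in 1:20) {
        T <- rlnorm(40, 5, 1); C <- rlnorm(40, 5, 1)
        names(T) <- names(C) <- sprintf("g%02d", 1:40)
        f <- runif(1, 0, 0.5)
        mixed <- (1 - f) * T + f * C
        back <- adjustSample(mixed, c(X = f), list(X = C))
        expect_equal(back, T, tolerance = 1e-9)
    }
})

test_that("the full adjustment workflow restores pure profiles and excludes hot samples", {
    cfg <- testSimConfig(seed = 23)
    pure <- generatePureProfiles(cfg)
    design <- cohortDesign(cfg)
    contam <- data.frame(
        sample_id = c("TU_s02", "TU_s03", "TAM_s02"),
        contaminant = c("TAM", "TAM", "TU"),
        frac = c(0.02, 0.08, 0.03))
    cohort <- generateContaminatedCohort(pure, design, contam,
                                         noiseSigma = 0)
    x <- cohort$se
    ## marker discovery on reference-grade (uncontaminated) replicates;
    ## discovery on a mostly-contaminated cohort would bias the target
    ## medians upward and starve the >50-fold criterion
    clean <- generateContaminatedCohort(pure, design, noiseSigma = 0)$se
    ## top-ranked candidates are the contaminant-exclusive genes (target
    ## reference exactly 0), for which the per-marker percentage formula is
    ## unbiased — exact recovery needs target-silent markers
    k <- cfg$nExclusivePerType
    sets <- list(
        suppressWarnings(selectContaminationMarkers(clean, "TU", "TAM",
                                                    topN = k)),
        suppressWarnings(selectContaminationMarkers(clean, "TAM", "TU",
                                                    topN = k)))
    res <- runAdjustment(x, sets)

    ## the 8% sample violates the 4% TU threshold and is gone
    expect_identical(excludedSamples(res$table), "TU_s03")
    expect_false("TU_s03" %in% colnames(res$adjusted))

    ## the 2% TU sample is restored to the pure profile
    adj <- tpm(res$adjusted)[, "TU_s02"]
    pureTU <- pure$profiles[, "TU"]
    expect_equal(adj, pureTU, tolerance = 1e-6)

    ## estimates match truth on noise-free mixtures
    est <- contaminationEstimates(res$table)
    e2 <- est$estimated_percent[est$sample_id == "TU_s02" &
                                est$contaminant == "TAM"]
    expect_equal(e2, 2, tolerance = 1e-9)

    ## no negatives; columns renormalized
    expect_true(all(tpm(res$adjusted) >= 0))
    expect_equal(colSums(tpm(res$adjusted)),
                 rep(1e6, ncol(res$adjusted)), ignore_attr = TRUE,
                 tolerance = 1e-6)

    ## determinism: rerun gives identical output
    res2 <- runAdjustment(x, sets)
    expect_identical(tpm(res$adjusted), tpm(res2$adjusted))
})

test_that("adjustment suppresses contaminant marker expression in target samples", {
    cfg <- testSimConfig(seed = 31)
    pure <- generatePureProfiles(cfg)
    design <- cohortDesign(cfg)
    contam <- data.frame(sample_id = "TU_s02", contaminant = "TAM",
                         frac = 0.03)
    cohort <- generateContaminatedCohort(pure, design, contam,
                                         noiseSigma = 0.1)
    x <- cohort$se
    sets <- list(selectContaminationMarkers(x, "TU", "TAM"))
    res <- runAdjustment(x, sets)
    mg <- markerGenes(sets[[1L]])
    before <- tpm(x)[mg, "TU_s02"]
    after <- tpm(res$adjusted)[mg, "TU_s02"]
    ## compare on the TPM-proportion scale to discount renormalization
    expect_true(all(after / 1e6 <= before / 1e6 + 1e-9))
})
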