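test_that("expression calls use a strict median TPM threshold", {
    med <- list(TU = c(2.0, 2.01, 0), TAM = c(1, 5, 0))
    x <- makeMedianSE(med, genes = c("gA", "gB", "gC"))
    ce <- callExpressed(x, tpmThreshold = 2)
    expect_false(ce$expressed["gA", "TU"])   # exactly 2 is not expressed
    expect_true(ce$expressed["gB", "TU"])
    expect_true(ce$expressed["gB", "TAM"])
    expect_false(any(ce$expressed["gC", ]))  # expressed nowhere
})

test_that("selectivity classification follows the strict fold-change rule", {
    types <- c("TU", "TAM", "TAT", "ADI", "MESO", "CAF")
    med <- list(
        TU  = c(cafsel = 10, sharedg = 50, stroma3 = 5,  tusel = 100),
        TAM = c(cafsel = 10, sharedg = 10, stroma3 = 5,  tusel = 3),
        TAT = c(cafsel = 5,  sharedg = 10, stroma3 = 5,  tusel = 3),
        ADI = c(cafsel = 10, sharedg = 10, stroma3 = 60, tusel = 3),
        MESO = c(cafsel = 10, sharedg = 10, stroma3 = 60, tusel = 3),
        CAF = c(cafsel = 100, sharedg = 49, stroma3 = 60, tusel = 3))
    x <- makeMedianSE(med)
    sel <- classifySelectivity(x)
    calls <- sel$calls
    cat2 <- stats::setNames(calls$category, calls$gene)

    ## CAF 100 vs all others <= 10: stroma-selective, CAF only
    expect_identical(unname(cat2["cafsel"]), "host_stroma")
    expect_identical(calls$selective_for[calls$gene == "cafsel"], "CAF")
    ## TU 50 vs CAF 49: below 5-fold, shared
    expect_identical(unname(cat2["sharedg"]), "shared")
    ## ADI = MESO = CAF = 60, others <= 5: stroma-selective, all three
    expect_identical(unname(cat2["stroma3"]), "host_stroma")
    expect_setequal(strsplit(calls$selective_for[
        calls$gene == "stroma3"], ";")[[1]], c("ADI", "MESO", "CAF"))
    ## TU 100 vs max host 3: tumour-selective
    expect_identical(unname(cat2["tusel"]), "tumour")

    ## partition completeness: mutually exclusive categories cover all
    ## expressed genes
    counts <- sel$counts
    expect_identical(unname(counts["tumour"] + counts["host"] +
                            counts["shared"]), unname(counts["expressed"]))
    expect_identical(unname(counts["host_stroma"] + counts["host_immune"] +
                            counts["host_shared"]), unname(counts["host"]))
})

test_that("receptor target scores reproduce the hand-computed examples", {
    med <- list(A = c(R1 = 10, R2 = 0, R3 = 10, L1 = 5, L2 = 5),
                B = c(R1 = 0, R2 = 10, R3 = 5, L1 = 5, L2 = 5))
    ## two pseudo cell types via TU (A) and CAF (B)
    m <- cbind(TU_1 = med$A, CAF_1 = med$B)
    x <- makeSE(m, c("TU", "CAF"))

    ## example 1: R1 only in A, R2 only in B -> both cell types score 1
    map1 <- LigandReceptorMap(c("L1", "L1"), c("R1", "R2"))
    s1 <- receptorTargetScores(map1, x)
    expect_equal(unname(s1["L1", c("TU", "CAF")]), c(1, 1),
                 tolerance = 1e-12)

    ## example 2: R1 = {10, 10}, R3 = {10, 5}: normalized sums {1.5, 2} ...
    map2 <- LigandReceptorMap(c("L2", "L2"), c("R3", "R2"))
    ## R3 = {A:10, B:5} -> {1, 0.5}; R2 = {A:0, B:10} -> {0, 1}
    ## sums {A:1, B:1.5} -> scores {A: 2/3, B: 1}
    s2 <- receptorTargetScores(map2, x)
    expect_equal(unname(s2["L2", c("TU", "CAF")]), c(1 / 1.5, 1),
                 tolerance = 1e-12)

    ## canonical worked case {A:0.5, B:1}: R1' = {10,10}, R2' = {0,5}
    m3 <- cbind(TU_1 = c(Ra = 10, Rb = 0, L = 5),
                CAF_1 = c(Ra = 10, Rb = 5, L = 5))
    x3 <- makeSE(m3, c("TU", "CAF"))
    s3 <- receptorTargetScores(LigandReceptorMap(c("L", "L"),
                                                 c("Ra", "Rb")), x3)
    expect_equal(unname(s3["L", c("TU", "CAF")]), c(0.5, 1),
                 tolerance = 1e-12)

    ## single receptor expressed only in one type
    s4 <- receptorTargetScores(LigandReceptorMap("L1", "R1"), x)
    expect_equal(unname(s4["L1", c("TU", "CAF")]), c(1, 0))

    ## all receptors absent -> zero row; warns about the dropped receptor
    ## and about the ligand left without receptors
    w <- capture_warnings(s5 <- receptorTargetScores(
        LigandReceptorMap("L1", "NOPE"), x))
    expect_match(w, "absent|no receptor", all = TRUE)
    expect_equal(unname(s5["L1", ]), c(0, 0))
})

test_that("receptor scores are invariant to uniform receptor rescaling", {
    set.seed(9)
    types <- c("TU", "TAM", "ADI", "CAF")
    for (i in 1:25) {
        nrec <- sample(2:4, 1)
        m <- matrix(rlnorm(nrec * length(types), 2, 1), nrow = nrec,
                    dimnames = list(sprintf("R%d", seq_len(nrec)),
                                    paste0(types, "_1")))
        x <- makeSE(m, types)
        map <- LigandReceptorMap(rep("L", nrec), rownames(m))
        base <- suppressWarnings(receptorTargetScores(map, x))
        scale <- runif(nrec, 0.1, 10)
        x2 <- makeSE(m * scale, types)
        rescaled <- suppressWarnings(receptorTargetScores(map, x2))
        expect_equal(base, rescaled, tolerance = 1e-9)
    }
})

test_that("the metastasis network emits edges per the receptor threshold rules", {
    m <- cbind(TU_1 = c(LIG = 0.1, REC = 5, UNF = 50, REC2 = 2.0),
               CAF_1 = c(LIG = 80, REC = 0.1, UNF = 50, REC2 = 0.1))
    x <- makeSE(m, c("TU", "CAF"))
    sel <- classifySelectivity(x)

    ## flagged CAF ligand with receptor on TU at 5 TPM -> edge CAF -> TU
    map <- LigandReceptorMap("LIG", "REC", metastasis = TRUE)
    net <- buildMetastasisNetwork(sel, map, x)
    expect_identical(net$source_cell_type, "CAF")
    expect_identical(net$target_cell_type, "TU")

    ## receptor median exactly at the threshold -> no edge (strict)
    map2 <- LigandReceptorMap("LIG", "REC2", metastasis = TRUE)
    expect_identical(nrow(buildMetastasisNetwork(sel, map2, x)), 0L)

    ## unflagged ligand -> no edge regardless of expression
    map3 <- LigandReceptorMap("UNF", "REC", metastasis = FALSE)
    expect_identical(nrow(buildMetastasisNetwork(sel, map3, x)), 0L)
})

test_that("planted ligand-target structure is recovered exactly on a clean cohort", {
    cfg <- testSimConfig(seed = 17)
    pure <- generatePureProfiles(cfg)
    cohort <- generateContaminatedCohort(pure, cohortDesign(cfg),
                                         noiseSigma = 0)
    lrs <- generateLigandReceptorSecretome(cfg, pure)
    sel <- classifySelectivity(cohort$se,
                               genes = intersect(ligands(lrs$map),
                                                 rownames(cohort$se)))
    net <- buildMetastasisNetwork(sel, lrs$map, cohort$se)
    got <- unique(net[, c("source_cell_type", "ligand",
                          "target_cell_type")])
    truth <- lrs$truth$ligands
    expect_identical(nrow(got), nrow(truth))
    key <- function(d, a, b, c) sort(paste(d[[a]], d[[b]], d[[c]]))
    expect_identical(key(got, "source_cell_type", "ligand",
                         "target_cell_type"),
                     sort(paste(truth$producer, truth$ligand, truth$target)))
    ## every planted target scores 1 for its ligand
    expect_true(all(net$receptor_score == 1))
})
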