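#' Simulation configuration
#'
#' Parameters of the synthetic-data generators. Defaults emulate the study
#' conditions the pipeline targets: six sorted cell populations, log-normal
#' baseline expression, planted 100-fold marker genes, multiplicative
#' log-normal measurement noise of sigma 0.2 on the natural-log scale,
#' six matched patient pairs with planted 8-fold shifts, and an LFQ model
#' in which detection probability rises logistically with log TPM.
#'
#' @param seed mandatory integer seed; every generator is a pure function
#'   of (config, seed).
#' @param nGenes genes in the cohort matrix (default 2000).
#' @param cellTypes simulated cell types (default the six TME populations).
#' @param nMarkersPerType planted marker genes per cell type (default 30,
#'   so a full 25-gene contamination set can be selected per pair).
#' @param markerFold marker enrichment of the owning cell type
#'   (default 100).
#' @param markerBaseMeanlog,markerBaseSdlog log-normal parameters of the
#'   marker genes' non-owner baseline (defaults log(50), 0.25; keeps the
#'   contaminant median above 10 TPM).
#' @param baselineMeanlog,baselineSdlog log-normal parameters of ordinary
#'   genes (defaults log(20), 1).
#' @param noiseSigma multiplicative log-normal noise sigma for cohort
#'   samples (default 0.2).
#' @param samplesPerType cohort samples per cell type (default 4).
#' @param nPairGenes,nPairs,nDEGenes,deFold,pairNoiseSigma,patientSigma,pairBaselineMeanlog
#'   matched-pair design: genes (1000), patient pairs (6), planted
#'   differentially expressed genes (50), planted fold (8), residual noise
#'   sigma (0.3), shared patient-effect sigma (0.5), baseline meanlog
#'   (log(50)).
#' @param nExclusivePerType per cell type, genes expressed essentially only
#'   by that type (default 12; owner level log-normal with meanlog
#'   \code{exclusiveMeanlog}, other types at \code{exclusiveOffTpm}). These
#'   model strictly cell-type-exclusive transcripts and carry the planted
#'   ligand/receptor structure.
#' @param exclusiveMeanlog,exclusiveOffTpm see \code{nExclusivePerType}
#'   (defaults log(200) and 0: strictly silent off the owner, which makes
#'   them ideal contamination markers — the target reference is exactly
#'   zero).
#' @param nLigands,receptorsPerLigand ligand/receptor design (defaults 12
#'   ligands, 2 receptors each, planted on a single target cell type).
#' @param nSecretomeProteins,detectionMidpointTpm,detectionSlope,lfqSlope,lfqIntercept,lfqNoiseSigma,lfqSamples
#'   secretome design: proteins scored (200), logistic detection midpoint
#'   in TPM (10) and slope (2, on log10 TPM), affine-log LFQ model
#'   lfq = lfqSlope * log10(TPM + 1) + lfqIntercept + noise (1, 3, 0.3),
#'   samples per timepoint (3).
#' @return A list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(seed,
                             nGenes = 2000L,
                             cellTypes = c("TU", "TAM", "TAT", "ADI",
                                           "MESO", "CAF"),
                             nMarkersPerType = 30L,
                             markerFold = 100,
                             markerBaseMeanlog = log(50),
                             markerBaseSdlog = 0.25,
                             baselineMeanlog = log(20),
                             baselineSdlog = 1,
                             noiseSigma = 0.2,
                             samplesPerType = 4L,
                             nExclusivePerType = 12L,
                             exclusiveMeanlog = log(200),
                             exclusiveOffTpm = 0,
                             nPairGenes = 1000L, nPairs = 6L,
                             nDEGenes = 50L, deFold = 8,
                             pairNoiseSigma = 0.3, patientSigma = 0.5,
                             pairBaselineMeanlog = log(50),
                             nLigands = 12L, receptorsPerLigand = 2L,
                             nSecretomeProteins = 200L,
                             detectionMidpointTpm = 10,
                             detectionSlope = 2,
                             lfqSlope = 1, lfqIntercept = 3,
                             lfqNoiseSigma = 0.3, lfqSamples = 3L) {
    if (missing(seed) || is.null(seed) || is.na(seed))
        stop("a seed is mandatory")
    cfg <- as.list(environment())
    cfg$seed <- as.integer(seed)
    if ((cfg$nMarkersPerType + cfg$nExclusivePerType) *
        length(cfg$cellTypes) > cfg$nGenes)
        stop("marker demands exceed nGenes")
    structure(cfg, class = "SimulationConfig")
}

## Evaluate expr under a fixed seed without disturbing the caller's RNG.
.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

#' Generate pure per-cell-type expression profiles
#'
#' Each cell type receives a TPM-normalized profile sharing a common
#' log-normal baseline, with its planted marker genes boosted
#' \code{markerFold}-fold. Marker genes double as contamination markers of
#' their owner when it contaminates another type: they are strongly
#' enriched in the owner and expressed above 10 TPM everywhere.
#'
#' @param config a [simulationConfig()].
#' @return A list: \code{profiles} (gene x cell-type TPM matrix),
#'   \code{markers} and \code{exclusives} (named lists of planted marker /
#'   exclusive genes per cell type) and \code{config}.
#' @export
generatePureProfiles <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    .withSeed(config$seed, {
        n <- config$nGenes
        types <- config$cellTypes
        genes <- sprintf("G%04d", seq_len(n))
        base <- stats::rlnorm(n, config$baselineMeanlog, config$baselineSdlog)
        k <- config$nMarkersPerType
        ke <- config$nExclusivePerType
        nm <- k * length(types)
        markers <- list(); exclusives <- list()
        for (i in seq_along(types)) {
            idx <- ((i - 1L) * k + 1L):(i * k)
            base[idx] <- stats::rlnorm(k, config$markerBaseMeanlog,
                                       config$markerBaseSdlog)
            markers[[types[i]]] <- genes[idx]
            eidx <- nm + ((i - 1L) * ke + 1L):(i * ke)
            exclusives[[types[i]]] <- genes[eidx]
        }
        profiles <- matrix(base, nrow = n, ncol = length(types),
                           dimnames = list(genes, types))
        for (i in seq_along(types)) {
            idx <- ((i - 1L) * k + 1L):(i * k)
            profiles[idx, i] <- profiles[idx, i] * config$markerFold
            eidx <- nm + ((i - 1L) * ke + 1L):(i * ke)
            profiles[eidx, ] <- config$exclusiveOffTpm
            profiles[eidx, i] <- stats::rlnorm(ke, config$exclusiveMeanlog,
                                               config$markerBaseSdlog)
        }
        profiles <- renormalizeTpm(profiles)
        list(profiles = profiles, markers = markers,
             exclusives = exclusives, config = config)
    })
}

#' Default cohort design for simulated samples
#'
#' \code{samplesPerType} samples per cell type; tumour and immune cells are
#' placed in ascites, stromal cells in omentum, each sample from its own
#' patient.
#'
#' @param config a [simulationConfig()].
#' @return data.frame: sample_id, cell_type, compartment, patient_id,
#'   is_reference.
#' @export
cohortDesign <- function(config) {
    types <- config$cellTypes
    comp <- ifelse(types %in% c("ADI", "MESO", "CAF"), "omentum", "ascites")
    rows <- list()
    for (i in seq_along(types)) {
        for (j in seq_len(config$samplesPerType)) {
            rows[[length(rows) + 1L]] <- data.frame(
                sample_id = sprintf("%s_s%02d", types[i], j),
                cell_type = types[i], compartment = comp[i],
                patient_id = sprintf("P%s%02d", types[i], j),
                is_reference = FALSE)
        }
    }
    do.call(rbind, rows)
}

#' Generate a contaminated cohort with known mixing fractions
#'
#' Every sample is a convex mixture on the TPM simplex:
#' (1 - sum f) x own pure profile + sum over contaminants of f_c x the
#' contaminant's pure profile, followed by multiplicative log-normal noise
#' and (optionally) renormalization — mirroring how cross-contamination
#' manifests in within-sample-normalized data.
#'
#' @param pure result of [generatePureProfiles()].
#' @param design data.frame as from [cohortDesign()].
#' @param contamination data.frame with columns sample_id, contaminant,
#'   frac (true mixing fractions; omitted samples are pure). Fractions must
#'   sum to < 1 per sample.
#' @param noiseSigma multiplicative noise sigma (default from the config;
#'   0 gives noise-free mixtures).
#' @param renormalize renormalize columns after noise (default TRUE).
#' @param seed seed for the noise draw (default config seed + 1).
#' @return A list: \code{se} (\linkS4class{TpmExperiment}) and \code{truth}
#'   (the contamination design).
#' @export
generateContaminatedCohort <- function(pure, design,
                                       contamination = NULL,
                                       noiseSigma = pure$config$noiseSigma,
                                       renormalize = TRUE,
                                       seed = pure$config$seed + 1L) {
    profiles <- pure$profiles
    if (is.null(contamination))
        contamination <- data.frame(sample_id = character(),
                                    contaminant = character(),
                                    frac = numeric())
    m <- matrix(0, nrow = nrow(profiles), ncol = nrow(design),
                dimnames = list(rownames(profiles), design$sample_id))
    for (i in seq_len(nrow(design))) {
        s <- design$sample_id[i]
        own <- design$cell_type[i]
        rows <- contamination[contamination$sample_id == s, , drop = FALSE]
        fsum <- sum(rows$frac)
        if (fsum >= 1) stop("fractions sum to >= 1 for sample ", s)
        col <- (1 - fsum) * profiles[, own]
        for (j in seq_len(nrow(rows)))
            col <- col + rows$frac[j] * profiles[, rows$contaminant[j]]
        m[, i] <- col
    }
    if (noiseSigma > 0)
        m <- .withSeed(seed, m * exp(matrix(
            stats::rnorm(length(m), 0, noiseSigma), nrow = nrow(m))))
    if (renormalize) m <- renormalizeTpm(m)
    list(se = TpmExperiment(m, design), truth = contamination)
}

#' Generate matched compartment pairs with planted fold changes
#'
#' Simulates \code{nPairs} patients, each contributing one omentum and one
#' ascites tumour-cell sample. Expression shares a per-patient, per-gene
#' log-normal factor (so pairing is informative); the first
#' \code{nDEGenes} genes carry a planted fold change of \code{deFold} in
#' the omentum sample, alternating up and down; all values receive
#' multiplicative log-normal noise.
#'
#' @param config a [simulationConfig()].
#' @param renormalize renormalize columns to TPM (default TRUE).
#' @return A list: \code{se} (\linkS4class{TpmExperiment}), \code{pairs}
#'   (matched-pair data.frame) and \code{truth} (gene, fold, direction).
#' @export
generateMatchedPairs <- function(config, renormalize = TRUE) {
    stopifnot(inherits(config, "SimulationConfig"))
    .withSeed(config$seed + 2L, {
        n <- config$nPairGenes
        np <- config$nPairs
        genes <- sprintf("PG%04d", seq_len(n))
        base <- stats::rlnorm(n, config$pairBaselineMeanlog, 1)
        fold <- rep(1, n)
        if (config$nDEGenes > 0) {
            idx <- seq_len(config$nDEGenes)
            fold[idx] <- ifelse(idx %% 2L == 1L, config$deFold,
                                1 / config$deFold)
        }
        m <- matrix(0, nrow = n, ncol = 2L * np)
        ids <- character(2L * np); compv <- character(2L * np)
        pidv <- character(2L * np)
        for (p in seq_len(np)) {
            patient <- exp(stats::rnorm(n, 0, config$patientSigma))
            noiseA <- exp(stats::rnorm(n, 0, config$pairNoiseSigma))
            noiseB <- exp(stats::rnorm(n, 0, config$pairNoiseSigma))
            m[, 2L * p - 1L] <- base * patient * fold * noiseA
            m[, 2L * p] <- base * patient * noiseB
            ids[2L * p - 1L] <- sprintf("omTU_P%02d", p)
            ids[2L * p] <- sprintf("ascTU_P%02d", p)
            compv[c(2L * p - 1L, 2L * p)] <- c("omentum", "ascites")
            pidv[c(2L * p - 1L, 2L * p)] <- sprintf("P%02d", p)
        }
        dimnames(m) <- list(genes, ids)
        if (renormalize) m <- renormalizeTpm(m)
        design <- data.frame(sample_id = ids, cell_type = "TU",
                             compartment = compv, patient_id = pidv,
                             is_reference = FALSE)
        se <- TpmExperiment(m, design)
        truth <- data.frame(gene = genes, fold = fold,
                            direction = ifelse(fold > 1, "up",
                                        ifelse(fold < 1, "down", "null")))
        list(se = se, pairs = matchedPairs(se, "TU"), truth = truth)
    })
}

#' Generate ligand/receptor annotation and a matched secretome
#'
#' Builds a \linkS4class{LigandReceptorMap} with planted single-target
#' structure over pure profiles: ligand i is one of its producer cell
#' type's exclusive genes, and its receptors are exclusive genes of the
#' planted target cell type (hence expressed essentially only there). All
#' ligands are metastasis-flagged. The LFQ table emulates a secretome experiment on
#' one cell type: detection probability follows a logistic curve in log10
#' TPM (midpoint \code{detectionMidpointTpm}, slope \code{detectionSlope}),
#' and detected proteins get late-timepoint LFQ values from the affine-log
#' model with baseline (0 h) values of 0.
#'
#' @param config a [simulationConfig()].
#' @param pure result of [generatePureProfiles()].
#' @param secretomeCellType cell type whose profile drives the LFQ model
#'   (default \code{"CAF"}).
#' @return A list: \code{map}, \code{lfq} (LFQ table data.frame) and
#'   \code{truth} (ligand/producer/target table, per-protein detection
#'   probability and detection outcome).
#' @export
generateLigandReceptorSecretome <- function(config, pure,
                                            secretomeCellType = "CAF") {
    stopifnot(inherits(config, "SimulationConfig"))
    types <- config$cellTypes
    nt <- length(types)
    used <- stats::setNames(rep(0L, nt), types)

    takeMarkers <- function(type, k) {
        pool <- pure$exclusives[[type]]
        if (used[[type]] + k > length(pool))
            stop("not enough planted exclusive genes of ", type,
                 " for the ligand/receptor design")
        out <- pool[used[[type]] + seq_len(k)]
        used[[type]] <<- used[[type]] + k
        out
    }

    lig <- character(); recL <- list(); producer <- character()
    target <- character()
    for (i in seq_len(config$nLigands)) {
        prod <- types[(i - 1L) %% nt + 1L]
        tgt <- types[i %% nt + 1L]
        lig[i] <- takeMarkers(prod, 1L)
        recL[[i]] <- takeMarkers(tgt, config$receptorsPerLigand)
        producer[i] <- prod
        target[i] <- tgt
    }
    map <- LigandReceptorMap(rep(lig, lengths(recL)), unlist(recL),
                             metastasis = TRUE)
    ligTruth <- data.frame(ligand = lig, producer = producer, target = target)

    prof <- pure$profiles[, secretomeCellType]
    .withSeed(config$seed + 3L, {
        prots <- sample(rownames(pure$profiles),
                        min(config$nSecretomeProteins,
                            nrow(pure$profiles)))
        tpmv <- prof[prots]
        pdet <- stats::plogis(config$detectionSlope *
                              (log10(tpmv) - log10(config$detectionMidpointTpm)))
        detected <- stats::rbinom(length(prots), 1L, pdet) == 1L
        rows <- list()
        for (j in seq_along(prots)) {
            for (s in seq_len(config$lfqSamples)) {
                late <- if (detected[j])
                    config$lfqSlope * log10(tpmv[j] + 1) +
                        config$lfqIntercept +
                        stats::rnorm(1L, 0, config$lfqNoiseSigma)
                else 0
                rows[[length(rows) + 1L]] <- data.frame(
                    protein = prots[j], sample = sprintf("cm%02d", s),
                    timepoint = "t_late", lfq = late,
                    peptide_detected = detected[j])
                rows[[length(rows) + 1L]] <- data.frame(
                    protein = prots[j], sample = sprintf("cm%02d", s),
                    timepoint = "t0", lfq = 0,
                    peptide_detected = detected[j])
            }
        }
        lfq <- do.call(rbind, rows)
        list(map = map, lfq = lfq,
             truth = list(ligands = ligTruth,
                          detectionProb = stats::setNames(pdet, prots),
                          detected = stats::setNames(detected, prots),
                          secretomeCellType = secretomeCellType))
    })
}
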