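#' Pipeline configuration
#'
#' Aggregates input paths and every analysis threshold, with the workflow's
#' standard values as defaults, so a zero-override configuration reproduces
#' the canonical analysis. Any override is echoed into the run manifest.
#'
#' @param matrixPath,metaPath TPM matrix and sample annotation TSVs
#'   (required).
#' @param exclusionPath gene-exclusion list (NULL = packaged default
#'   asset).
#' @param lrMapPath ligand-receptor table TSV (optional; selectivity is
#'   restricted to its ligands and the network stage runs when present).
#' @param lfqPath LFQ table TSV (optional; enables the concordance stage).
#' @param survivalPath survival-statistics TSV (optional; enables the
#'   survival-filter stage).
#' @param outDir output directory for stage TSVs, report and manifest.
#' @param seed integer seed recorded in the manifest.
#' @param contaminantMap named list mapping each target cell type to its
#'   contaminating cell types (NULL = every other cell type present).
#' @param expressionTpm,selectivityFc strict thresholds for expression
#'   calls (2 TPM) and selectivity (5-fold).
#' @param deCellType,deFc,deTpm,deAlpha matched differential expression:
#'   cell type compared between compartments (TU), fold change (3), TPM
#'   floor (3), nominal alpha (0.05).
#' @param markerTopN,markerMinFold,markerMinContTpm,markerOffset
#'   contamination-marker selection: set size (25), fold change (50),
#'   contaminant TPM floor (10), offset (0.001).
#' @param receptorTpm receptor expression threshold for network edges (2).
#' @param secretomeCellType cell type whose transcriptome anchors the
#'   concordance stage (CAF).
#' @param preferCompartment compartment preference for per-cell-type
#'   medians (omentum).
#' @param adjustment an [adjustmentConfig()].
#' @return A list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(matrixPath, metaPath, exclusionPath = NULL,
                           lrMapPath = NULL, lfqPath = NULL,
                           survivalPath = NULL, outDir = "tmenet_run",
                           seed = 1L, contaminantMap = NULL,
                           expressionTpm = 2, selectivityFc = 5,
                           deCellType = "TU", deFc = 3, deTpm = 3,
                           deAlpha = 0.05, markerTopN = 25L,
                           markerMinFold = 50, markerMinContTpm = 10,
                           markerOffset = 0.001, receptorTpm = 2,
                           secretomeCellType = "CAF",
                           preferCompartment = "omentum",
                           adjustment = adjustmentConfig()) {
    cfg <- as.list(environment())
    structure(cfg, class = "PipelineConfig")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML key-value file whose keys match the arguments of
#' [pipelineConfig()]; unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A \code{"PipelineConfig"} list.
#' @export
readPipelineConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    known <- names(formals(pipelineConfig))
    bad <- setdiff(names(vals), known)
    if (length(bad))
        stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    if (!is.null(vals$adjustment))
        vals$adjustment <- do.call(adjustmentConfig, vals$adjustment)
    do.call(pipelineConfig, vals)
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

## Only JSON-serialisable, order-stable parameter echo for the manifest.
.echoParams <- function(cfg) {
    keep <- !vapply(cfg, is.function, logical(1L))
    cfg <- cfg[keep]
    cfg$adjustment <- unclass(cfg$adjustment)
    lapply(cfg, function(v) if (is.null(v)) NA else unclass(v))
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates load, gene exclusion, contamination-marker selection,
#' contamination estimation with sample exclusion, linear adjustment,
#' selectivity classification, network assembly, matched differential
#' expression, secretome concordance and the survival filter. Every stage
#' writes TSV output into the run directory; a manifest records stage
#' parameters and MD5 hashes of all outputs, so identical configuration
#' and inputs yield an identical manifest. Optional stages whose inputs
#' are absent are skipped and noted in the manifest.
#'
#' @param config a [pipelineConfig()] (or path to a YAML file for
#'   [readPipelineConfig()]).
#' @return Invisibly, the run directory. Side effects: stage TSVs,
#'   \code{report.json}, \code{manifest.json}.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- readPipelineConfig(config)
    stopifnot(inherits(config, "PipelineConfig"))
    out <- config$outDir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(seed = config$seed, params = .echoParams(config),
                     stages = list(), skipped = character())
    report <- list()
    addStage <- function(name, files, info = NULL) {
        hashes <- as.list(tools::md5sum(file.path(out, files)))
        names(hashes) <- files
        manifest$stages[[name]] <<- list(outputs = hashes, info = info)
    }

    x <- .stage("load", readTpmMatrix(config$matrixPath, config$metaPath))

    patterns <- if (is.null(config$exclusionPath)) defaultExclusionList()
                else readExclusionList(config$exclusionPath)
    x <- .stage("exclude_genes", excludeGenes(x, patterns))
    writeTpmMatrix(x, file.path(out, "matrix_filtered.tsv"))
    addStage("exclude_genes", "matrix_filtered.tsv",
             list(genes_kept = nrow(x)))

    cmap <- config$contaminantMap
    if (is.null(cmap)) {
        types <- unique(cellType(x))
        cmap <- lapply(stats::setNames(nm = types),
                       function(t) setdiff(types, t))
    }
    markerSets <- .stage("markers", {
        sets <- list()
        for (tgt in names(cmap))
            for (cnt in cmap[[tgt]])
                sets[[paste(tgt, cnt, sep = ".")]] <-
                    suppressWarnings(selectContaminationMarkers(
                        x, tgt, cnt, topN = config$markerTopN,
                        minFoldChange = config$markerMinFold,
                        minContaminantTpm = config$markerMinContTpm,
                        offset = config$markerOffset))
        Filter(function(ms) length(ms) > 0L, sets)
    })
    writeMarkerSets(markerSets, file.path(out, "marker_sets.tsv"))
    addStage("markers", "marker_sets.tsv",
             list(n_sets = length(markerSets)))

    adj <- .stage("adjust", runAdjustment(x, markerSets, config$adjustment))
    writeContaminationTable(adj$table, file.path(out, "contamination.tsv"))
    writeTpmMatrix(adj$adjusted, file.path(out, "matrix_adjusted.tsv"),
                   file.path(out, "meta_adjusted.tsv"))
    addStage("adjust", c("contamination.tsv", "matrix_adjusted.tsv",
                         "meta_adjusted.tsv"),
             list(excluded = as.list(excludedSamples(adj$table)),
                  references = as.list(adj$references)))
    report$excluded_samples <- excludedSamples(adj$table)
    ax <- adj$adjusted

    lrMap <- NULL
    if (!is.null(config$lrMapPath))
        lrMap <- .stage("load_lr_map", readLigandReceptorMap(config$lrMapPath))
    selGenes <- if (!is.null(lrMap))
        intersect(ligands(lrMap), rownames(ax)) else NULL
    sel <- .stage("selectivity", classifySelectivity(
        ax, fc = config$selectivityFc, tpmThreshold = config$expressionTpm,
        preferCompartment = config$preferCompartment, genes = selGenes))
    utils::write.table(sel$calls, file.path(out, "selectivity_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    addStage("selectivity", "selectivity_calls.tsv",
             list(counts = as.list(sel$counts)))
    report$selectivity_counts <- as.list(sel$counts)
    report$stroma_subset_counts <- as.list(sel$stromaSubsets)

    if (!is.null(lrMap)) {
        net <- .stage("network", {
            scores <- suppressWarnings(receptorTargetScores(
                lrMap, ax, config$preferCompartment))
            utils::write.table(
                data.frame(ligand = rownames(scores), scores,
                           check.names = FALSE),
                file.path(out, "receptor_scores.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
            buildMetastasisNetwork(sel, lrMap, ax,
                                   receptorTpm = config$receptorTpm,
                                   preferCompartment =
                                       config$preferCompartment)
        })
        writeNetwork(net, file.path(out, "network_edges.tsv"),
                     file.path(out, "network_nodes.tsv"))
        addStage("network", c("receptor_scores.tsv", "network_edges.tsv",
                              "network_nodes.tsv"),
                 list(n_edges = nrow(net)))
        report$network_edge_count <- nrow(net)
    } else manifest$skipped <- c(manifest$skipped,
                                 "network (no ligand-receptor map)")

    pairs <- matchedPairs(ax, config$deCellType)
    if (nrow(pairs) >= 3L) {
        de <- .stage("differential", pairedDE(
            ax, pairs, fc = config$deFc, tpmMin = config$deTpm,
            alpha = config$deAlpha))
        utils::write.table(de, file.path(out, "de_results.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        rho <- .stage("differential",
                      matchedCorrelation(ax, pairs, "spearman"))
        addStage("differential", "de_results.tsv",
                 list(n_pairs = nrow(pairs), n_called = sum(de$called),
                      spearman = rho))
        report$de_called <- sum(de$called)
        report$de_pairs <- nrow(pairs)
        report$matched_spearman <- rho
    } else manifest$skipped <- c(manifest$skipped,
                                 "differential (fewer than 3 matched pairs)")

    if (!is.null(config$lfqPath)) {
        conc <- .stage("concordance", {
            lfq <- readLfqTable(config$lfqPath)
            calls <- callSecretome(lfq)
            med <- cellTypeMedians(ax, config$preferCompartment)
            if (!config$secretomeCellType %in% colnames(med))
                stop("secretome cell type '", config$secretomeCellType,
                     "' absent from matrix")
            tpmMed <- med[, config$secretomeCellType]
            lfqLate <- lfq[lfq$timepoint == "t_late", , drop = FALSE]
            lfqMed <- tapply(lfqLate$lfq, lfqLate$protein, stats::median)
            shared <- intersect(names(tpmMed), calls$protein)
            edges <- c(0, 0.3, 3, 30, 300,
                       max(tpmMed[shared], 300) + 1)
            list(calls = calls,
                 rate = detectionRateByExpression(tpmMed[shared], calls,
                                                  edges),
                 rho = rnaProteinCorrelation(tpmMed, lfqMed,
                                             "spearman", calls))
        })
        utils::write.table(conc$calls, file.path(out, "secretome_calls.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(conc$rate, file.path(out, "detection_rate.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        addStage("concordance", c("secretome_calls.tsv",
                                  "detection_rate.tsv"),
                 list(rna_protein_spearman = conc$rho))
        report$secretome_size <- sum(conc$calls$in_secretome)
        report$rna_protein_spearman <- conc$rho
    } else manifest$skipped <- c(manifest$skipped,
                                 "concordance (no LFQ table)")

    if (!is.null(config$survivalPath)) {
        surv <- .stage("survival", survivalFilter(
            readSurvivalStats(config$survivalPath)))
        utils::write.table(surv, file.path(out, "survival_filtered.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        addStage("survival", "survival_filtered.tsv",
                 list(n_kept = nrow(surv)))
        report$survival_kept <- nrow(surv)
        report$survival_short <- sum(surv$direction == "short survival")
    } else manifest$skipped <- c(manifest$skipped,
                                 "survival (no survival table)")

    jsonlite::write_json(report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    addStage("report", "report.json")
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(out)
}

#' Read the machine-readable summary of a pipeline run
#'
#' @param runDir run directory written by [runPipeline()].
#' @return Named list: partition counts, excluded samples, network edge
#'   count, differential-expression counts and correlations. An incomplete
#'   run (missing report) is an error; skipped stages simply lack their
#'   entries.
#' @export
pipelineReport <- function(runDir) {
    path <- file.path(runDir, "report.json")
    if (!file.exists(path))
        stop("no report.json in '", runDir, "' — incomplete run")
    jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a fully simulated study into a directory
#'
#' Generates a complete synthetic input set with known ground truth — a
#' contaminated cohort (including matched tumour pairs and one
#' over-contaminated sample), a planted ligand-receptor map, an LFQ table
#' and the packaged survival-statistics table — and writes them as the
#' TSVs a [runPipeline()] configuration points at. Truth tables are
#' written alongside for validation.
#'
#' @param config a [simulationConfig()].
#' @param dir output directory.
#' @return Invisibly, a [pipelineConfig()] pointing at the written files.
#' @export
simulateStudy <- function(config, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    pure <- generatePureProfiles(config)
    types <- config$cellTypes

    ## Tumour cells: 4 patients x both compartments (matched pairs);
    ## other types: samplesPerType samples each.
    rows <- list()
    for (p in 1:4)
        for (comp in c("omentum", "ascites"))
            rows[[length(rows) + 1L]] <- data.frame(
                sample_id = sprintf("TU_%s_P%02d",
                                    substr(comp, 1L, 2L), p),
                cell_type = "TU", compartment = comp,
                patient_id = sprintf("P%02d", p), is_reference = FALSE)
    for (t in setdiff(types, "TU"))
        for (j in seq_len(config$samplesPerType))
            rows[[length(rows) + 1L]] <- data.frame(
                sample_id = sprintf("%s_s%02d", t, j), cell_type = t,
                compartment = if (t %in% c("ADI", "MESO", "CAF"))
                    "omentum" else "ascites",
                patient_id = sprintf("P%s%02d", t, j),
                is_reference = FALSE)
    design <- do.call(rbind, rows)

    ## contamination touches a minority of samples per type so that marker
    ## discovery on the cohort itself (median-based) stays uncompromised
    contam <- rbind(
        data.frame(sample_id = "TU_om_P02", contaminant = "TAM",
                   frac = 0.02),
        data.frame(sample_id = "TU_as_P03", contaminant = "TAM",
                   frac = 0.03),
        data.frame(sample_id = "TU_om_P04", contaminant = "TAM",
                   frac = 0.08),
        data.frame(sample_id = "TAM_s02", contaminant = "TU", frac = 0.02),
        data.frame(sample_id = "TAT_s02", contaminant = "TU", frac = 0.02),
        data.frame(sample_id = "ADI_s02", contaminant = "MESO",
                   frac = 0.04),
        data.frame(sample_id = "MESO_s02", contaminant = "TU",
                   frac = 0.03),
        data.frame(sample_id = "CAF_s02", contaminant = "TU", frac = 0.03))

    cohort <- generateContaminatedCohort(pure, design, contam)
    writeTpmMatrix(cohort$se, file.path(dir, "matrix.tsv"),
                   file.path(dir, "meta.tsv"))
    utils::write.table(contam, file.path(dir, "contamination_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    lrs <- generateLigandReceptorSecretome(config, pure)
    utils::write.table(lrTable(lrs$map), file.path(dir, "lr_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(lrs$lfq, file.path(dir, "lfq.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(lrs$truth$ligands,
                       file.path(dir, "ligand_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    file.copy(system.file("extdata", "stroma_survival_stats.tsv",
                          package = "TMEnet", mustWork = TRUE),
              file.path(dir, "survival_stats.tsv"), overwrite = TRUE)
    yaml::write_yaml(unclass(config)[!vapply(unclass(config), is.function,
                                             logical(1L))],
                     file.path(dir, "sim_config.yaml"))

    invisible(pipelineConfig(
        matrixPath = file.path(dir, "matrix.tsv"),
        metaPath = file.path(dir, "meta.tsv"),
        lrMapPath = file.path(dir, "lr_map.tsv"),
        lfqPath = file.path(dir, "lfq.tsv"),
        survivalPath = file.path(dir, "survival_stats.tsv"),
        outDir = file.path(dir, "run"), seed = config$seed,
        secretomeCellType = lrs$truth$secretomeCellType))
}
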