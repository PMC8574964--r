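#' Adjustment configuration
#'
#' Collects the knobs of the two-step contamination workflow: estimation /
#' sample exclusion, then linear unmixing.
#'
#' @param exclusionThreshold named numeric vector mapping cell types to the
#'   contamination percentage at or above which a sample is excluded
#'   (defaults: 4 for TU, TAM and TAT, 6 for ADI; MESO and CAF carry no
#'   threshold and are never excluded by default).
#' @param minimumPercent assumed minimal contamination percentages, either a
#'   single number applied to every (target, contaminant) pair or a named
#'   list of named vectors \code{minimumPercent[[target]][contaminant]}.
#'   Default 0: no floor. Sorting purity never reaches 100\%, so a study may
#'   assert a positive floor; the floor binds only when the marker-based
#'   estimate falls below it.
#' @param profileSource \code{"cohort_median"} (contaminant profile = median
#'   over the contaminant cell type's kept samples) or
#'   \code{"patient_matched"} (use the same patient's contaminant sample
#'   when one is available, cohort median otherwise).
#' @param adjustmentOrder \code{"descending_fraction"} (default; remove the
#'   largest estimated contaminant first) or \code{"given"} (order of the
#'   supplied marker sets).
#' @return A list of class \code{"AdjustmentConfig"}.
#' @export
adjustmentConfig <- function(exclusionThreshold = c(TU = 4, TAM = 4, TAT = 4,
                                                    ADI = 6),
                             minimumPercent = 0,
                             profileSource = c("cohort_median",
                                               "patient_matched"),
                             adjustmentOrder = c("descending_fraction",
                                                 "given")) {
    stopifnot(all(exclusionThreshold > 0), all(exclusionThreshold <= 100))
    structure(list(exclusionThreshold = exclusionThreshold,
                   minimumPercent = minimumPercent,
                   profileSource = match.arg(profileSource),
                   adjustmentOrder = match.arg(adjustmentOrder)),
              class = "AdjustmentConfig")
}

.minimumPercentFor <- function(config, target, contaminant) {
    mp <- config$minimumPercent
    if (is.numeric(mp) && length(mp) == 1L) return(unname(mp))
    val <- mp[[target]][contaminant]
    if (is.null(val) || is.na(val)) 0 else unname(val)
}

#' Choose the reference sample of a cell type
#'
#' The reference sample is the sample with the lowest levels of contaminating
#' marker RNA: among the target cell type's samples, the one minimizing the
#' sum over the relevant contamination marker sets of the per-set median
#' marker TPM. A user-pinned \code{is_reference} flag overrides the
#' automatic choice; ties break deterministically by sample identifier.
#'
#' @param x a \linkS4class{TpmExperiment}.
#' @param target target cell type.
#' @param markerSets list of \linkS4class{MarkerSet}s; sets whose
#'   \code{target} matches are used to score contamination.
#' @param honourFlag use a pinned \code{is_reference} sample when present
#'   (default TRUE).
#' @return A sample identifier.
#' @export
chooseReferenceSample <- function(x, target, markerSets, honourFlag = TRUE) {
    stopifnot(is(x, "TpmExperiment"))
    idx <- .typeColumns(x, target)
    if (!length(idx))
        stop("no samples of cell type '", target, "'")
    ids <- colnames(x)[idx]
    if (honourFlag) {
        pinned <- ids[isReference(x)[ids]]
        if (length(pinned)) return(sort(pinned)[1L])
    }
    relevant <- Filter(function(ms) ms@target == target && length(ms@genes),
                       markerSets)
    if (!length(relevant)) return(sort(ids)[1L])
    m <- tpm(x)
    score <- vapply(ids, function(s) {
        sum(vapply(relevant, function(ms) {
            stats::median(m[ms@genes, s])
        }, numeric(1L)))
    }, numeric(1L))
    ids[order(score, ids)][1L]
}

#' Estimate the contamination percentage of one sample
#'
#' For each marker gene g of the contamination marker set, the per-marker
#' percentage is
#' \deqn{pct_g = (TPM_{sample,g} - TPM_{target\,ref,g}) /
#'       TPM_{contaminant\,ref,g} \times 100,}
#' clamped to [0, 100]; the estimate is the median of the per-marker values,
#' floored at \code{floorPercent} (an assumed minimal contamination). The
#' returned value carries a \code{"floored"} attribute indicating whether
#' the floor was binding.
#'
#' @param sampleCol named TPM vector of the sample under assessment.
#' @param targetRefCol named TPM vector of the target-cell-type reference
#'   sample.
#' @param contRefCol named TPM vector of the contaminating cell type's
#'   reference sample.
#' @param markerSet contamination \linkS4class{MarkerSet}.
#' @param floorPercent assumed minimal contamination percentage (default 0).
#' @return Estimated percentage in [0, 100] with attribute \code{floored}.
#' @export
estimateContamination <- function(sampleCol, targetRefCol, contRefCol,
                                  markerSet, floorPercent = 0) {
    genes <- markerGenes(markerSet)
    if (!length(genes))
        stop("empty marker set for ", markerSet@contaminant, " in ",
             markerSet@target)
    s <- sampleCol[genes]
    tr <- targetRefCol[genes]
    cr <- contRefCol[genes]
    if (any(is.na(s)) || any(is.na(tr)) || any(is.na(cr)))
        stop("marker gene(s) absent from the supplied columns")
    drop <- cr == 0
    if (any(drop)) {
        warning(sum(drop), " marker(s) with zero contaminant reference ",
                "dropped for ", markerSet@contaminant, " in ",
                markerSet@target)
        s <- s[!drop]; tr <- tr[!drop]; cr <- cr[!drop]
    }
    if (!length(s))
        stop("all markers dropped: contaminant reference is zero throughout")
    pct <- pmin(pmax((s - tr) / cr * 100, 0), 100)
    med <- stats::median(pct)
    est <- max(med, floorPercent)
    attr(est, "floored") <- floorPercent > med
    est
}

#' Partition samples by the contamination exclusion rule
#'
#' A sample is excluded when the estimated contamination by \emph{any}
#' contaminating cell type is greater than or equal to its cell type's
#' threshold (default 4\% for TU/TAM/TAT, 6\% for ADI). Cell types without
#' a configured threshold (MESO, CAF by default) are never excluded.
#'
#' @param table a \linkS4class{ContaminationTable} (estimates filled).
#' @param config an [adjustmentConfig()].
#' @return The \linkS4class{ContaminationTable} with the \code{excluded}
#'   slot set; retrieve the verdict with [excludedSamples()].
#' @export
applyExclusion <- function(table, config = adjustmentConfig()) {
    stopifnot(is(table, "ContaminationTable"))
    est <- contaminationEstimates(table)
    thr <- config$exclusionThreshold
    excl <- character()
    for (s in unique(est$sample_id)) {
        rows <- est[est$sample_id == s, , drop = FALSE]
        ctype <- rows$cell_type[1L]
        if (!ctype %in% names(thr)) next
        if (any(rows$estimated_percent >= thr[[ctype]]))
            excl <- c(excl, s)
    }
    ContaminationTable(est, sort(unique(excl)))
}

#' Linearly unmix one sample column
#'
#' Removes contaminating expression iteratively: for each contaminant c in
#' \code{order}, the column is replaced by
#' \deqn{(col - frac_c \cdot profile_c) / (1 - frac_c).}
#' After all contaminants are removed, negative corrected values are set to
#' 0. The caller renormalizes the full matrix afterwards. By default
#' contaminants are removed in order of descending fraction; the order only
#' matters through second-order cross terms when several contaminants are
#' present.
#'
#' @param sampleCol named TPM vector.
#' @param fracs named numeric vector of contamination fractions in [0, 1).
#' @param profiles named list of contaminant profile vectors covering the
#'   same genes.
#' @param order character vector fixing the removal order; default
#'   descending fraction (ties by contaminant name).
#' @return The adjusted column (non-negative, not yet renormalized).
#' @examples
#' col <- c(g1 = 90, g2 = 10)
#' prof <- list(TAM = c(g1 = 500, g2 = 500))
#' adjustSample(col, c(TAM = 0.1), prof)  # (90-50)/0.9 = 44.44, 0 (clamped)
#' @export
adjustSample <- function(sampleCol, fracs, profiles, order = NULL) {
    if (any(fracs >= 1))
        stop("contamination fraction >= 1 for: ",
             paste(names(fracs)[fracs >= 1], collapse = ", "))
    if (any(fracs < 0))
        stop("negative contamination fraction")
    if (is.null(order))
        order <- names(fracs)[order(-fracs, names(fracs))]
    col <- sampleCol
    for (cnt in order) {
        f <- fracs[[cnt]]
        if (f == 0) next
        prof <- profiles[[cnt]]
        if (is.null(prof))
            stop("no contaminant profile for '", cnt, "'")
        col <- (col - f * prof[names(col)]) / (1 - f)
    }
    pmax(col, 0)
}

## Contaminant profile columns for the adjustment step.
.contaminantProfile <- function(x, contaminant, keptIds, patient, config) {
    ct <- cellType(x)
    pool <- intersect(names(ct)[ct == contaminant], keptIds)
    if (config$profileSource == "patient_matched") {
        pid <- patientId(x)
        matched <- pool[pid[pool] == patient]
        if (length(matched) == 1L) return(tpm(x)[, matched])
        if (length(matched) > 1L)
            return(apply(tpm(x)[, matched, drop = FALSE], 1L, stats::median))
    }
    if (!length(pool)) {
        pool <- names(ct)[ct == contaminant]
        warning("no kept '", contaminant,
                "' sample; profile taken over all its samples")
    }
    apply(tpm(x)[, pool, drop = FALSE], 1L, stats::median)
}

#' Run the full contamination-adjustment workflow
#'
#' Pipeline: (1) choose a reference sample per cell type (pinned flag or
#' lowest contaminating-marker RNA); (2) estimate the contamination of every
#' sample of each targeted cell type by each configured contaminant
#' ([estimateContamination()]); (3) exclude over-contaminated samples
#' ([applyExclusion()]); (4) unmix the kept samples ([adjustSample()]) using
#' cohort-median (or patient-matched) contaminant profiles; (5) clamp
#' negatives and renormalize.
#'
#' @param x a \linkS4class{TpmExperiment} (gene-filtered, renormalized).
#' @param markerSets list of contamination \linkS4class{MarkerSet}s; each
#'   (target, contaminant) pair present defines one estimation.
#' @param config an [adjustmentConfig()].
#' @return A list with elements \code{adjusted} (the adjusted
#'   \linkS4class{TpmExperiment}, excluded samples dropped), \code{table}
#'   (the \linkS4class{ContaminationTable}) and \code{references} (named
#'   vector of reference sample identifiers).
#' @export
runAdjustment <- function(x, markerSets, config = adjustmentConfig()) {
    stopifnot(is(x, "TpmExperiment"))
    markerSets <- Filter(function(ms) length(ms@genes) > 0L, markerSets)
    if (!length(markerSets))
        stop("no non-empty contamination marker sets supplied")
    ct <- cellType(x)
    m <- tpm(x)
    targets <- unique(vapply(markerSets, function(ms) ms@target, character(1L)))
    involved <- unique(c(targets,
                         vapply(markerSets, function(ms) ms@contaminant,
                                character(1L))))
    refs <- vapply(involved, function(t)
        chooseReferenceSample(x, t, markerSets), character(1L))

    rows <- list()
    for (ms in markerSets) {
        tgt <- ms@target; cnt <- ms@contaminant
        floorP <- .minimumPercentFor(config, tgt, cnt)
        for (s in colnames(x)[ct == tgt]) {
            est <- estimateContamination(m[, s], m[, refs[[tgt]]],
                                         m[, refs[[cnt]]], ms, floorP)
            rows[[length(rows) + 1L]] <- data.frame(
                sample_id = s, cell_type = tgt, contaminant = cnt,
                estimated_percent = as.numeric(est),
                floored = attr(est, "floored"))
        }
    }
    est <- do.call(rbind, rows)
    table <- applyExclusion(ContaminationTable(est), config)
    excl <- excludedSamples(table)
    kept <- setdiff(colnames(x), excl)

    estKept <- contaminationEstimates(table)
    estKept <- estKept[!estKept$sample_id %in% excl, , drop = FALSE]
    adj <- m[, kept, drop = FALSE]
    pid <- patientId(x)
    for (s in kept) {
        rowsS <- estKept[estKept$sample_id == s, , drop = FALSE]
        if (!nrow(rowsS)) next
        fracs <- stats::setNames(rowsS$estimated_percent / 100,
                                 rowsS$contaminant)
        fracs <- fracs[fracs > 0]
        if (!length(fracs)) next
        profiles <- lapply(stats::setNames(nm = names(fracs)), function(cnt)
            .contaminantProfile(x, cnt, kept, pid[[s]], config))
        order <- if (config$adjustmentOrder == "descending_fraction")
            names(fracs)[order(-fracs, names(fracs))] else names(fracs)
        adj[, s] <- adjustSample(adj[, s], fracs, profiles, order)
    }
    keptX <- x[, kept]
    assay(keptX, "tpm") <- renormalizeTpm(adj)
    list(adjusted = keptX, table = table, references = refs)
}

#' Write a ContaminationTable as TSV
#'
#' @param table a \linkS4class{ContaminationTable}.
#' @param path output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeContaminationTable <- function(table, path) {
    est <- contaminationEstimates(table)
    est$excluded <- est$sample_id %in% excludedSamples(table)
    utils::write.table(est, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
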