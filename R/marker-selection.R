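#' Marker selection criteria
#'
#' Thresholds for identity-marker selection. A gene qualifies as an identity
#' marker of a target cell type when (i) its median TPM across target
#' samples exceeds the cell-type-specific floor, (ii) the max/min spread
#' across target samples is at most \code{maxWithinSpread}-fold, and
#' (iii) the minimum TPM in the target set exceeds
#' \code{minCrossRatio}-fold the minimum TPM of every other cell type's
#' sample set. All inequalities are strict.
#'
#' @param medianFloor named numeric vector of per-cell-type median TPM
#'   floors. Defaults: 100 for TU/TAM/TAT, 1000 for ADI/MESO, 25 for CAF —
#'   the floors differ because adipocytes and mesothelial cells have few,
#'   very highly expressed distinguishing transcripts while fibroblast
#'   markers are comparatively weak.
#' @param maxWithinSpread maximum fold difference between minimum and
#'   maximum expression within the target sample set (default 10).
#' @param minCrossRatio minimum ratio between min(target) and every other
#'   cell type's minimum (default 10).
#' @return A list of class \code{"MarkerCriteria"}.
#' @export
markerCriteria <- function(medianFloor = c(TU = 100, TAM = 100, TAT = 100,
                                           ADI = 1000, MESO = 1000, CAF = 25),
                           maxWithinSpread = 10, minCrossRatio = 10) {
    stopifnot(all(medianFloor > 0), maxWithinSpread > 0, minCrossRatio > 0)
    structure(list(medianFloor = medianFloor,
                   maxWithinSpread = maxWithinSpread,
                   minCrossRatio = minCrossRatio),
              class = "MarkerCriteria")
}

## Column subset for one cell type, optionally preferring one compartment
## (falling back to all samples of the type when that compartment is absent).
.typeColumns <- function(x, type, preferCompartment = NULL) {
    ct <- cellType(x)
    idx <- which(ct == type)
    if (!is.null(preferCompartment)) {
        comp <- sampleCompartment(x)
        pref <- idx[comp[idx] == preferCompartment]
        if (length(pref)) idx <- pref
    }
    idx
}

#' Median TPM per gene and cell type
#'
#' @param x a \linkS4class{TpmExperiment}.
#' @param preferCompartment if non-NULL (e.g. \code{"omentum"}), use samples
#'   from that compartment for each cell type when available, falling back
#'   to the other compartment otherwise.
#' @param genes optional gene subset.
#' @return Numeric matrix, genes x cell types.
#' @export
cellTypeMedians <- function(x, preferCompartment = NULL, genes = NULL) {
    stopifnot(is(x, "TpmExperiment"))
    m <- tpm(x)
    if (!is.null(genes)) {
        miss <- setdiff(genes, rownames(m))
        if (length(miss))
            stop("gene(s) absent from matrix: ",
                 paste(utils::head(miss, 5L), collapse = ", "))
        m <- m[genes, , drop = FALSE]
    }
    types <- unique(cellType(x))
    out <- vapply(types, function(t) {
        idx <- .typeColumns(x, t, preferCompartment)
        apply(m[, idx, drop = FALSE], 1L, stats::median)
    }, numeric(nrow(m)))
    if (is.null(dim(out)))
        out <- matrix(out, nrow = nrow(m), dimnames = list(rownames(m), types))
    out
}

## Maximal leading alphabetic prefix, the default gene-family key
## (e.g. FCGR2A -> FCGR). Overridable via an explicit family map.
.geneFamily <- function(genes, familyMap = NULL) {
    pre <- sub("^([A-Za-z]*).*$", "\\1", genes)
    fam <- ifelse(nzchar(pre), pre, genes)
    if (!is.null(familyMap)) {
        hit <- genes %in% names(familyMap)
        fam[hit] <- familyMap[genes[hit]]
    }
    fam
}

#' Select cell-type identity markers
#'
#' Applies the three identity-marker criteria (see [markerCriteria()]) and
#' ranks passing genes by the cross-type minimum ratio, the most stringent of
#' the three. Optionally deduplicates to the top \code{nTop} markers from
#' distinct gene families (default family key: maximal leading alphabetic
#' prefix of the symbol).
#'
#' @param x a \linkS4class{TpmExperiment} (adjusted or raw).
#' @param target target cell type.
#' @param criteria a [markerCriteria()] list.
#' @param nTop if non-NULL, return only the top \code{nTop} markers from
#'   distinct gene families.
#' @param familyMap optional named character vector mapping gene symbols to
#'   family labels, overriding the prefix heuristic.
#' @return A \linkS4class{MarkerSet} (identity flavour; empty with a warning
#'   when no gene passes).
#' @export
selectIdentityMarkers <- function(x, target, criteria = markerCriteria(),
                                  nTop = NULL, familyMap = NULL) {
    stopifnot(is(x, "TpmExperiment"))
    m <- tpm(x)
    tgt <- .typeColumns(x, target)
    if (length(tgt) < 1L)
        stop("no samples of target cell type '", target, "'")
    others <- setdiff(unique(cellType(x)), target)
    floor <- criteria$medianFloor[[target]]
    if (is.null(floor) || is.na(floor))
        stop("no median TPM floor configured for cell type '", target, "'")

    tmat <- m[, tgt, drop = FALSE]
    medT <- apply(tmat, 1L, stats::median)
    minT <- apply(tmat, 1L, min)
    maxT <- apply(tmat, 1L, max)
    spread <- ifelse(minT > 0, maxT / minT, ifelse(maxT > 0, Inf, 1))
    otherMin <- vapply(others, function(t) {
        apply(m[, .typeColumns(x, t), drop = FALSE], 1L, min)
    }, numeric(nrow(m)))
    worstOtherMin <- apply(as.matrix(otherMin), 1L, max)
    ratio <- ifelse(minT > 0,
                    ifelse(worstOtherMin > 0, minT / worstOtherMin, Inf), 0)

    pass <- medT > floor & spread <= criteria$maxWithinSpread &
        ratio > criteria$minCrossRatio
    genes <- rownames(m)[pass]
    if (!length(genes)) {
        warning("no identity marker passes the criteria for '", target, "'")
        return(MarkerSet(target))
    }
    sc <- ratio[pass]
    ord <- order(-sc, genes)
    genes <- genes[ord]
    sc <- sc[ord]
    if (!is.null(nTop)) {
        fam <- .geneFamily(genes, familyMap)
        keep <- !duplicated(fam)
        genes <- genes[keep][seq_len(min(nTop, sum(keep)))]
        sc <- sc[keep][seq_len(length(genes))]
    }
    MarkerSet(target, NA_character_, genes, sc)
}

#' Select a contamination marker set
#'
#' Candidate genes must show a greater than \code{minFoldChange} median fold
#' change between contaminating and target cell type, computed with a
#' symmetric offset of \code{offset} on both medians to keep fold changes
#' finite and rankable, and a median expression above
#' \code{minContaminantTpm} TPM in the contaminating cell type. Candidates
#' are ranked by fold change (ties broken by gene symbol) and the top
#' \code{topN} are returned.
#'
#' @param x a \linkS4class{TpmExperiment}.
#' @param target cell type of interest.
#' @param contaminant contaminating cell type.
#' @param topN number of markers to keep (default 25; fewer are returned
#'   with a warning when fewer qualify).
#' @param minFoldChange fold-change threshold (default 50, strict).
#' @param minContaminantTpm contaminant median TPM floor (default 10,
#'   strict).
#' @param offset additive offset guarding zero medians (default 0.001).
#' @return A \linkS4class{MarkerSet} (contamination flavour).
#' @export
selectContaminationMarkers <- function(x, target, contaminant, topN = 25L,
                                       minFoldChange = 50,
                                       minContaminantTpm = 10,
                                       offset = 0.001) {
    stopifnot(is(x, "TpmExperiment"))
    m <- tpm(x)
    tgt <- .typeColumns(x, target)
    cnt <- .typeColumns(x, contaminant)
    if (!length(tgt) || !length(cnt))
        stop("samples of both '", target, "' and '", contaminant,
             "' are required")
    medT <- apply(m[, tgt, drop = FALSE], 1L, stats::median)
    medC <- apply(m[, cnt, drop = FALSE], 1L, stats::median)
    fc <- (medC + offset) / (medT + offset)
    pass <- fc > minFoldChange & medC > minContaminantTpm
    genes <- rownames(m)[pass]
    if (!length(genes)) {
        warning("no contamination marker passes for ", contaminant, " in ",
                target)
        return(MarkerSet(target, contaminant))
    }
    sc <- fc[pass]
    ord <- order(-sc, genes)
    genes <- genes[ord]
    sc <- sc[ord]
    if (length(genes) < topN)
        warning("only ", length(genes), " of the requested ", topN,
                " contamination markers qualify for ", contaminant, " in ",
                target)
    keep <- seq_len(min(topN, length(genes)))
    MarkerSet(target, contaminant, genes[keep], sc[keep])
}

#' Serialize marker sets as TSV
#'
#' @param markerSets a list of \linkS4class{MarkerSet} objects.
#' @param path output TSV path.
#' @return Invisibly, \code{path}.
#' @export
writeMarkerSets <- function(markerSets, path) {
    rows <- lapply(markerSets, function(ms) {
        if (!length(ms@genes)) return(NULL)
        data.frame(target = ms@target, contaminant = ms@contaminant,
                   rank = seq_along(ms@genes), gene = ms@genes,
                   score = ms@scores)
    })
    df <- do.call(rbind, rows)
    if (is.null(df))
        df <- data.frame(target = character(), contaminant = character(),
                         rank = integer(), gene = character(),
                         score = numeric())
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
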