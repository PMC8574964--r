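## Shared fixture builders. All fixtures are constructed in code; no files.

## TpmExperiment from a bare matrix; cell types / compartments recycled
## along columns, one patient per sample unless given.
makeSE <- function(m, cellTypes, compartments = NULL, patients = NULL,
                   isRef = FALSE) {
    if (is.null(colnames(m)))
        colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
    if (is.null(rownames(m)))
        rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
    ct <- rep_len(cellTypes, ncol(m))
    if (is.null(compartments))
        compartments <- ifelse(ct %in% c("ADI", "MESO", "CAF"),
                               "omentum", "ascites")
    md <- data.frame(sample_id = colnames(m),
                     cell_type = ct,
                     compartment = rep_len(compartments, ncol(m)),
                     patient_id = if (is.null(patients))
                         sprintf("p%02d", seq_len(ncol(m)))
                     else rep_len(patients, ncol(m)),
                     is_reference = rep_len(isRef, ncol(m)))
    TpmExperiment(m, md)
}

## One sample per cell type whose value IS the cell-type median; used for
## selectivity rule checks. `medians`: named list cell type -> numeric
## vector over the same genes.
makeMedianSE <- function(medians, genes = NULL) {
    types <- names(medians)
    m <- do.call(cbind, medians)
    if (!is.null(genes)) rownames(m) <- genes
    colnames(m) <- paste0(types, "_1")
    makeSE(m, types)
}

## Independent brute-force step-up FDR from the definition:
## for ordered p(1) <= ... <= p(m), q(i) = min_{j >= i} m * p(j) / j.
bruteForceBH <- function(p) {
    m <- length(p)
    ord <- order(p)
    ps <- p[ord]
    q <- numeric(m)
    for (i in seq_len(m)) {
        cand <- vapply(i:m, function(j) m * ps[j] / j, numeric(1))
        q[i] <- min(cand, 1)
    }
    out <- numeric(m)
    out[ord] <- q
    out
}

## Small default simulation config used across tests (kept light so the
## whole suite stays fast).
testSimConfig <- function(seed = 42, ...) {
    args <- list(seed = seed, nGenes = 500L, nMarkersPerType = 30L,
                 nExclusivePerType = 12L, samplesPerType = 3L)
    dots <- list(...)
    args[names(dots)] <- dots
    do.call(simulationConfig, args)
}
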