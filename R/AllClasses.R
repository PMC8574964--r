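#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assayNames colData
NULL

## Column-sum target of a TPM profile: transcripts per million.
.TPM_SCALE <- 1e6

## Sorted cell populations of the omental / ascites tumour microenvironment.
.CELL_TYPES <- c("TU", "TAM", "TAT", "ADI", "MESO", "CAF")
.COMPARTMENTS <- c("ascites", "omentum")

#' TpmExperiment: a TPM matrix with sample annotation
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a single
#' \code{"tpm"} assay (genes x samples, transcripts per million) and the
#' per-sample annotation required by the contamination-adjustment workflow:
#' \code{cell_type} (one of TU, TAM, TAT, ADI, MESO, CAF), \code{compartment}
#' (ascites or omentum), \code{patient_id} and \code{is_reference}.
#'
#' Validity requires unique gene symbols and sample identifiers, finite
#' non-negative TPM values, and a complete annotation record for every sample.
#'
#' @aliases TpmExperiment-class
#' @export
setClass("TpmExperiment", contains = "SummarizedExperiment")

setValidity("TpmExperiment", function(object) {
    msg <- character()
    if (!"tpm" %in% assayNames(object))
        msg <- c(msg, "assay 'tpm' is required")
    else {
        m <- assay(object, "tpm")
        if (any(!is.finite(m)))
            msg <- c(msg, "TPM values must be finite")
        else if (any(m < 0))
            msg <- c(msg, "TPM values must be non-negative")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object))) {
        dup <- unique(rownames(object)[duplicated(rownames(object))])
        msg <- c(msg, paste0("gene symbols must be present and unique",
                             if (length(dup)) paste0(" (duplicated: ",
                                 paste(utils::head(dup, 5L), collapse = ", "), ")")))
    }
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be present and unique")
    need <- c("cell_type", "compartment", "patient_id", "is_reference")
    miss <- setdiff(need, colnames(colData(object)))
    if (length(miss))
        msg <- c(msg, paste0("missing sample annotation column(s): ",
                             paste(miss, collapse = ", ")))
    else {
        ct <- colData(object)$cell_type
        bad <- setdiff(unique(as.character(ct)), .CELL_TYPES)
        if (length(bad))
            msg <- c(msg, paste0("unknown cell_type value(s): ",
                                 paste(bad, collapse = ", ")))
        cp <- colData(object)$compartment
        badc <- setdiff(unique(as.character(cp)), .COMPARTMENTS)
        if (length(badc))
            msg <- c(msg, paste0("unknown compartment value(s): ",
                                 paste(badc, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' Construct a TpmExperiment
#'
#' @param tpm numeric matrix of TPM values, genes in rows (rownames = gene
#'   symbols), samples in columns (colnames = sample identifiers).
#' @param sampleData data.frame with one row per sample and columns
#'   \code{sample_id}, \code{cell_type}, \code{compartment},
#'   \code{patient_id}, \code{is_reference}. Rows are matched to matrix
#'   columns by \code{sample_id}.
#'
#' @return A \linkS4class{TpmExperiment}.
#' @examples
#' m <- matrix(c(6e5, 4e5, 3e5, 7e5), nrow = 2,
#'             dimnames = list(c("ACTB", "EPCAM"), c("s1", "s2")))
#' md <- data.frame(sample_id = c("s1", "s2"), cell_type = "TU",
#'                  compartment = "omentum", patient_id = c("p1", "p2"),
#'                  is_reference = FALSE)
#' TpmExperiment(m, md)
#' @export
TpmExperiment <- function(tpm, sampleData) {
    tpm <- as.matrix(tpm)
    storage.mode(tpm) <- "double"
    sampleData <- as.data.frame(sampleData)
    need <- c("sample_id", "cell_type", "compartment", "patient_id",
              "is_reference")
    miss <- setdiff(need, colnames(sampleData))
    if (length(miss))
        stop("sampleData lacks column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(sampleData$sample_id))
        stop("duplicated sample_id in sampleData")
    absent <- setdiff(colnames(tpm), sampleData$sample_id)
    if (length(absent))
        stop("no metadata for sample(s): ", paste(absent, collapse = ", "))
    sampleData <- sampleData[match(colnames(tpm), sampleData$sample_id), ,
                             drop = FALSE]
    cd <- DataFrame(cell_type = as.character(sampleData$cell_type),
                    compartment = as.character(sampleData$compartment),
                    patient_id = as.character(sampleData$patient_id),
                    is_reference = as.logical(sampleData$is_reference),
                    row.names = colnames(tpm))
    new("TpmExperiment",
        SummarizedExperiment(assays = list(tpm = tpm), colData = cd))
}

#' MarkerSet: an ordered marker gene list
#'
#' Holds the ranked marker genes tying a target cell type (and, for
#' contamination marker sets, a contaminating cell type) to its estimator.
#' Genes are ordered by decreasing ranking score: the cross-type minimum
#' ratio for identity markers, the offset fold change for contamination
#' markers.
#'
#' @aliases MarkerSet-class
#' @export
setClass("MarkerSet",
    representation(target = "character", contaminant = "character",
                   genes = "character", scores = "numeric"))

setValidity("MarkerSet", function(object) {
    msg <- character()
    if (length(object@target) != 1L)
        msg <- c(msg, "target must be a single cell type")
    if (length(object@contaminant) != 1L)
        msg <- c(msg, "contaminant must be length 1 (NA for identity sets)")
    if (length(object@genes) != length(object@scores))
        msg <- c(msg, "genes and scores must have equal length")
    if (anyDuplicated(object@genes))
        msg <- c(msg, "marker genes must be unique")
    if (length(object@scores) > 1L && is.unsorted(rev(object@scores)))
        msg <- c(msg, "scores must be non-increasing")
    if (length(msg)) msg else TRUE
})

MarkerSet <- function(target, contaminant = NA_character_, genes = character(),
                      scores = numeric()) {
    new("MarkerSet", target = as.character(target),
        contaminant = as.character(contaminant),
        genes = as.character(genes), scores = as.numeric(scores))
}

#' ContaminationTable: per-sample contamination estimates and verdicts
#'
#' Rows of (sample, contaminating cell type, estimated percentage, floored)
#' plus the set of samples excluded as over-contaminated.
#'
#' @aliases ContaminationTable-class
#' @export
setClass("ContaminationTable",
    representation(estimates = "data.frame", excluded = "character"))

setValidity("ContaminationTable", function(object) {
    msg <- character()
    need <- c("sample_id", "cell_type", "contaminant", "estimated_percent",
              "floored")
    miss <- setdiff(need, colnames(object@estimates))
    if (length(miss))
        msg <- c(msg, paste0("estimates lacks column(s): ",
                             paste(miss, collapse = ", ")))
    else {
        p <- object@estimates$estimated_percent
        if (any(p < 0 | p > 100))
            msg <- c(msg, "estimated_percent must lie in [0, 100]")
    }
    if (length(msg)) msg else TRUE
})

ContaminationTable <- function(estimates, excluded = character()) {
    new("ContaminationTable", estimates = as.data.frame(estimates),
        excluded = as.character(excluded))
}

#' LigandReceptorMap: ligand to cognate-receptor annotation
#'
#' Many-to-many mapping of cytokine / growth-factor ligand genes to their
#' cognate receptor genes, with an optional per-ligand metastasis-association
#' flag used when assembling the metastasis signalling network.
#'
#' @aliases LigandReceptorMap-class
#' @export
setClass("LigandReceptorMap", representation(table = "data.frame"))

setValidity("LigandReceptorMap", function(object) {
    msg <- character()
    need <- c("ligand", "receptor", "metastasis")
    miss <- setdiff(need, colnames(object@table))
    if (length(miss))
        msg <- c(msg, paste0("table lacks column(s): ",
                             paste(miss, collapse = ", ")))
    else {
        if (any(is.na(object@table$ligand)) || any(is.na(object@table$receptor)))
            msg <- c(msg, "ligand and receptor entries must be non-missing")
        if (nrow(object@table) &&
            any(!nzchar(object@table$ligand) | !nzchar(object@table$receptor)))
            msg <- c(msg, "ligand and receptor symbols must be non-empty")
    }
    if (length(msg)) msg else TRUE
})

#' @param ligand,receptor character vectors of equal length (one row per
#'   ligand-receptor pair).
#' @param metastasis logical vector flagging metastasis-associated ligands
#'   (recycled along pairs).
#' @rdname LigandReceptorMap-class
#' @export
LigandReceptorMap <- function(ligand, receptor, metastasis = FALSE) {
    tab <- data.frame(ligand = as.character(ligand),
                      receptor = as.character(receptor),
                      metastasis = rep_len(as.logical(metastasis),
                                           length(ligand)))
    tab <- unique(tab)
    new("LigandReceptorMap", table = tab)
}
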