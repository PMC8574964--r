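#' @describeIn accessors TPM assay matrix of a TpmExperiment.
#' @export
setMethod("tpm", "TpmExperiment", function(x, ...) assay(x, "tpm"))

#' @describeIn accessors cell type of each sample.
#' @export
setMethod("cellType", "TpmExperiment", function(x, ...) {
    stats::setNames(colData(x)$cell_type, colnames(x))
})

#' @describeIn accessors compartment (ascites / omentum) of each sample.
#' @export
setMethod("sampleCompartment", "TpmExperiment", function(x, ...) {
    stats::setNames(colData(x)$compartment, colnames(x))
})

#' @describeIn accessors patient identifier of each sample.
#' @export
setMethod("patientId", "TpmExperiment", function(x, ...) {
    stats::setNames(colData(x)$patient_id, colnames(x))
})

#' @describeIn accessors user-pinned reference flag of each sample.
#' @export
setMethod("isReference", "TpmExperiment", function(x, ...) {
    stats::setNames(colData(x)$is_reference, colnames(x))
})

setMethod("show", "TpmExperiment", function(object) {
    cat("TpmExperiment with", nrow(object), "genes and", ncol(object),
        "samples\n")
    tab <- table(cellType(object), sampleCompartment(object))
    cat("samples per cell type x compartment:\n")
    print(tab)
    invisible(NULL)
})

#' @describeIn accessors ranked marker genes of a MarkerSet.
#' @export
setMethod("markerGenes", "MarkerSet", function(x, ...) x@genes)

#' @describeIn accessors ranking scores of a MarkerSet.
#' @export
setMethod("markerScores", "MarkerSet", function(x, ...) {
    stats::setNames(x@scores, x@genes)
})

setMethod("show", "MarkerSet", function(object) {
    kind <- if (is.na(object@contaminant)) "identity"
            else paste0("contamination (", object@contaminant, " in ",
                        object@target, ")")
    cat("MarkerSet [", kind, "] for ", object@target, ": ",
        length(object@genes), " gene(s)\n", sep = "")
    if (length(object@genes))
        cat("  top: ", paste(utils::head(object@genes, 5L), collapse = ", "),
            "\n", sep = "")
    invisible(NULL)
})

setMethod("length", "MarkerSet", function(x) length(x@genes))

#' @describeIn accessors per-sample contamination estimate rows.
#' @export
setMethod("contaminationEstimates", "ContaminationTable",
          function(x, ...) x@estimates)

#' @describeIn accessors samples excluded as over-contaminated.
#' @export
setMethod("excludedSamples", "ContaminationTable", function(x, ...) x@excluded)

setMethod("show", "ContaminationTable", function(object) {
    cat("ContaminationTable:", nrow(object@estimates), "estimate(s),",
        length(object@excluded), "excluded sample(s)\n")
    if (length(object@excluded))
        cat("  excluded:", paste(object@excluded, collapse = ", "), "\n")
    invisible(NULL)
})

#' @describeIn accessors unique ligand symbols of a LigandReceptorMap.
#' @export
setMethod("ligands", "LigandReceptorMap", function(x, ...) {
    unique(x@table$ligand)
})

#' @describeIn accessors receptor genes cognate to one ligand.
#' @export
setMethod("receptorsOf", "LigandReceptorMap", function(x, ligand, ...) {
    unique(x@table$receptor[x@table$ligand == ligand])
})

setMethod("show", "LigandReceptorMap", function(object) {
    cat("LigandReceptorMap:", length(unique(object@table$ligand)),
        "ligand(s),", length(unique(object@table$receptor)),
        "receptor(s),", nrow(object@table), "pair(s);",
        sum(object@table$metastasis[!duplicated(object@table$ligand)]),
        "metastasis-flagged ligand(s)\n")
    invisible(NULL)
})

#' Flag table of a LigandReceptorMap
#'
#' @param x a \linkS4class{LigandReceptorMap}.
#' @return data.frame with columns ligand, receptor, metastasis.
#' @export
lrTable <- function(x) {
    stopifnot(is(x, "LigandReceptorMap"))
    x@table
}
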