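#' Accessors for TMEnet classes
#'
#' \code{tpm} returns the TPM assay matrix; \code{cellType},
#' \code{sampleCompartment}, \code{patientId} and \code{isReference} return
#' the per-sample annotation vectors; \code{markerGenes} and
#' \code{markerScores} the ranked genes of a \linkS4class{MarkerSet};
#' \code{contaminationEstimates} and \code{excludedSamples} the contents of a
#' \linkS4class{ContaminationTable}; \code{ligands} and \code{receptorsOf}
#' query a \linkS4class{LigandReceptorMap}.
#'
#' @param x an object of the documented class.
#' @param ... further arguments passed to methods.
#' @return See the individual method descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tpm", function(x, ...) standardGeneric("tpm"))

#' @rdname accessors
#' @export
setGeneric("cellType", function(x, ...) standardGeneric("cellType"))

#' @rdname accessors
#' @export
setGeneric("sampleCompartment",
           function(x, ...) standardGeneric("sampleCompartment"))

#' @rdname accessors
#' @export
setGeneric("patientId", function(x, ...) standardGeneric("patientId"))

#' @rdname accessors
#' @export
setGeneric("isReference", function(x, ...) standardGeneric("isReference"))

#' @rdname accessors
#' @export
setGeneric("markerGenes", function(x, ...) standardGeneric("markerGenes"))

#' @rdname accessors
#' @export
setGeneric("markerScores", function(x, ...) standardGeneric("markerScores"))

#' @rdname accessors
#' @export
setGeneric("contaminationEstimates",
           function(x, ...) standardGeneric("contaminationEstimates"))

#' @rdname accessors
#' @export
setGeneric("excludedSamples",
           function(x, ...) standardGeneric("excludedSamples"))

#' @rdname accessors
#' @export
setGeneric("ligands", function(x, ...) standardGeneric("ligands"))

#' @param ligand a single ligand gene symbol.
#' @rdname accessors
#' @export
setGeneric("receptorsOf",
           function(x, ligand, ...) standardGeneric("receptorsOf"))

#' Renormalize a TPM profile
#'
#' Rescales every sample column so that it sums to one million, preserving
#' within-sample gene proportions. The operation is idempotent; an all-zero
#' sample is an error (it has no proportions to preserve).
#'
#' @param x a \linkS4class{TpmExperiment} or numeric matrix (genes x samples).
#' @return An object of the same class with columns summing to 1e6.
#' @examples
#' m <- matrix(c(1, 1, 2, 0), nrow = 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' renormalizeTpm(m)
#' @export
setGeneric("renormalizeTpm", function(x, ...) standardGeneric("renormalizeTpm"))
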