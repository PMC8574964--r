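#' Read a TPM matrix and its sample annotation
#'
#' Reads a tab-separated TPM table (first column gene symbols, header row of
#' sample identifiers) together with a sample annotation table and
#' cross-validates them: every matrix column must have exactly one annotation
#' record, and gene symbols must be unique.
#'
#' @param path TSV file of TPM values, genes in rows.
#' @param metaPath TSV file with columns \code{sample_id}, \code{cell_type},
#'   \code{compartment}, \code{patient_id}, \code{is_reference}.
#' @return A \linkS4class{TpmExperiment}.
#' @seealso [writeTpmMatrix()], [excludeGenes()], [renormalizeTpm()]
#' @export
readTpmMatrix <- function(path, metaPath) {
    raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(raw) < 2L)
        stop("TPM table '", path, "' needs a gene column plus >=1 sample")
    genes <- as.character(raw[[1L]])
    if (anyDuplicated(genes)) {
        dup <- unique(genes[duplicated(genes)])
        stop("duplicated gene symbol(s) in '", path, "': ",
             paste(dup, collapse = ", "))
    }
    m <- as.matrix(raw[, -1L, drop = FALSE])
    storage.mode(m) <- "double"
    if (any(!is.finite(m))) {
        bad <- which(!is.finite(m), arr.ind = TRUE)[1L, ]
        stop("non-numeric or non-finite TPM at gene '", genes[bad[1L]],
             "', sample '", colnames(m)[bad[2L]], "'")
    }
    rownames(m) <- genes
    meta <- utils::read.delim(metaPath, header = TRUE, check.names = FALSE,
                              stringsAsFactors = FALSE)
    TpmExperiment(m, meta)
}

#' Write a TPM matrix (and optionally its annotation) as TSV
#'
#' @param x a \linkS4class{TpmExperiment}.
#' @param path output TSV path for the matrix.
#' @param metaPath optional output TSV path for the sample annotation.
#' @return Invisibly, \code{path}.
#' @export
writeTpmMatrix <- function(x, path, metaPath = NULL) {
    stopifnot(is(x, "TpmExperiment"))
    df <- data.frame(gene = rownames(x), tpm(x), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(metaPath)) {
        md <- data.frame(sample_id = colnames(x),
                         cell_type = cellType(x),
                         compartment = sampleCompartment(x),
                         patient_id = patientId(x),
                         is_reference = isReference(x))
        utils::write.table(md, metaPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}

#' @describeIn renormalizeTpm method for a bare matrix.
#' @export
setMethod("renormalizeTpm", "matrix", function(x, ...) {
    cs <- colSums(x)
    zero <- which(cs <= 0)
    if (length(zero))
        stop("sample(s) with no positive values cannot be renormalized: ",
             paste(colnames(x)[zero], collapse = ", "))
    sweep(x, 2L, cs / .TPM_SCALE, "/")
})

#' @describeIn renormalizeTpm method for a TpmExperiment.
#' @export
setMethod("renormalizeTpm", "TpmExperiment", function(x, ...) {
    assay(x, "tpm") <- renormalizeTpm(tpm(x))
    x
})

#' Read a gene-exclusion list
#'
#' One gene symbol or glob-style pattern (\code{*}, \code{?}) per line;
#' blank lines and lines starting with \code{#} are ignored. Matching is
#' case-sensitive and deterministic: a symbol either matches a pattern or it
#' does not.
#'
#' @param path text file of symbols / patterns.
#' @return Character vector of patterns.
#' @export
readExclusionList <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Default gene-exclusion asset
#'
#' The exclusion list applied before all downstream analyses: mitochondrial
#' genes (\code{MT-*}), mitochondrial ribosomal genes (\code{MRPL*},
#' \code{MRPS*}), cytosolic 40S/60S ribosomal genes (\code{RPL*},
#' \code{RPS*}), non-protein-coding gene families (\code{MIR*},
#' \code{LINC*}), histone genes (library-protocol dependent; see the methods
#' vignette), and the fixed set of genes whose quantification differs
#' between total-RNA and poly(A) library protocols. Shipped as a package
#' asset because recomputing the protocol-discordant set would require a
#' paired-library experiment.
#'
#' @return Character vector of symbols / patterns.
#' @export
defaultExclusionList <- function() {
    readExclusionList(system.file("extdata", "default_gene_exclusion.txt",
                                  package = "TMEnet", mustWork = TRUE))
}

.matchExclusion <- function(genes, patterns) {
    hit <- rep(FALSE, length(genes))
    for (p in patterns) {
        if (grepl("[*?]", p))
            hit <- hit | grepl(utils::glob2rx(p), genes)
        else
            hit <- hit | genes == p
    }
    hit
}

#' Remove excluded genes and renormalize
#'
#' Drops every gene matching the exclusion list (exact symbols or glob
#' patterns) and renormalizes the remaining profile to TPM, so that each
#' sample again sums to one million.
#'
#' @param x a \linkS4class{TpmExperiment}.
#' @param exclusion character vector of symbols / patterns, e.g. from
#'   [readExclusionList()] or [defaultExclusionList()].
#' @return The filtered, renormalized \linkS4class{TpmExperiment}.
#' @examples
#' m <- matrix(c(5e5, 3e5, 1.5e5, 5e4), ncol = 1,
#'             dimnames = list(c("A", "B", "C", "MT-CO1"), "s1"))
#' md <- data.frame(sample_id = "s1", cell_type = "TU",
#'                  compartment = "omentum", patient_id = "p1",
#'                  is_reference = FALSE)
#' x <- TpmExperiment(m, md)
#' tpm(excludeGenes(x, "MT-*"))
#' @export
excludeGenes <- function(x, exclusion) {
    stopifnot(is(x, "TpmExperiment"))
    hit <- .matchExclusion(rownames(x), exclusion)
    if (all(hit))
        stop("exclusion list removes every gene")
    renormalizeTpm(x[!hit, ])
}
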