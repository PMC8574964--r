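#' Read a label-free-quantitation (LFQ) table
#'
#' TSV with columns \code{protein} (gene-symbol mapped), \code{sample},
#' \code{timepoint} (\code{t0} or \code{t_late}), \code{lfq} (log-scale
#' intensity) and \code{peptide_detected} (logical). Each (protein, sample,
#' timepoint) combination must be unique.
#'
#' @param path TSV path.
#' @return Validated data.frame.
#' @export
readLfqTable <- function(path) {
    tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("protein", "sample", "timepoint", "lfq", "peptide_detected")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
        stop("LFQ table lacks column(s): ", paste(miss, collapse = ", "))
    bad <- setdiff(unique(tab$timepoint), c("t0", "t_late"))
    if (length(bad))
        stop("unknown timepoint value(s): ", paste(bad, collapse = ", "))
    key <- paste(tab$protein, tab$sample, tab$timepoint)
    if (anyDuplicated(key))
        stop("duplicated (protein, sample, timepoint) combination(s)")
    tab$peptide_detected <- as.logical(tab$peptide_detected)
    tab
}

#' Secretion signal of a protein
#'
#' Difference between the late-timepoint and 0-h LFQ values (both on the
#' same, typically log10, scale). A missing 0-h value is treated as 0
#' (non-detection at baseline) by default, or the pair can be dropped.
#'
#' @param lfqT0 baseline (0 h) LFQ value(s); NA = missing.
#' @param lfqLate late-timepoint LFQ value(s).
#' @param missingT0 \code{"zero"} (default) or \code{"drop"} (returns NA).
#' @return \code{lfqLate - lfqT0} element-wise.
#' @examples
#' secretionSignal(5, 7)      # 2
#' secretionSignal(NA, 6)     # 6
#' @export
secretionSignal <- function(lfqT0, lfqLate, missingT0 = c("zero", "drop")) {
    missingT0 <- match.arg(missingT0)
    if (missingT0 == "zero")
        lfqT0 <- ifelse(is.na(lfqT0), 0, lfqT0)
    lfqLate - lfqT0
}

#' Call the secretome
#'
#' A protein is "in secretome" when a peptide group was detected in at
#' least one sample and its median late-timepoint LFQ signal is strictly
#' greater than its median 0-h signal. Proteins with no 0-h rows use a
#' baseline median of 0 (absence).
#'
#' @param table LFQ data.frame from [readLfqTable()].
#' @return data.frame: protein, in_secretome, secretion_signal (median late
#'   minus median baseline).
#' @export
callSecretome <- function(table) {
    proteins <- sort(unique(table$protein))
    res <- lapply(proteins, function(pr) {
        rows <- table[table$protein == pr, , drop = FALSE]
        late <- rows$lfq[rows$timepoint == "t_late"]
        base <- rows$lfq[rows$timepoint == "t0"]
        medLate <- if (length(late)) stats::median(late) else 0
        medBase <- if (length(base)) stats::median(base) else 0
        detected <- any(rows$peptide_detected)
        data.frame(protein = pr,
                   in_secretome = detected && medLate > medBase,
                   secretion_signal = medLate - medBase)
    })
    do.call(rbind, res)
}

#' Secretome detection rate by RNA expression
#'
#' Fraction of genes per TPM bin whose protein was called in the secretome;
#' quantifies how protein detectability rises with transcript abundance.
#'
#' @param tpmMedians named numeric vector of median TPM per gene (typically
#'   restricted to a cytokine / growth-factor list).
#' @param calls data.frame from [callSecretome()].
#' @param binEdges increasing numeric vector of TPM bin edges covering the
#'   observed range.
#' @return data.frame: bin label, lower, upper, n, fraction (NA for empty
#'   bins).
#' @export
detectionRateByExpression <- function(tpmMedians, calls, binEdges) {
    if (is.unsorted(binEdges, strictly = TRUE))
        stop("binEdges must be strictly increasing")
    genes <- intersect(names(tpmMedians), calls$protein)
    if (!length(genes))
        stop("no overlap between tpmMedians names and called proteins")
    tpmv <- tpmMedians[genes]
    if (any(tpmv < binEdges[1L]) || any(tpmv > binEdges[length(binEdges)]))
        stop("binEdges do not cover the observed TPM range")
    inSec <- stats::setNames(calls$in_secretome, calls$protein)[genes]
    bin <- cut(tpmv, binEdges, include.lowest = TRUE)
    n <- as.vector(table(bin))
    frac <- vapply(levels(bin), function(b) {
        sel <- bin == b
        if (!any(sel)) NA_real_ else mean(inSec[sel])
    }, numeric(1L))
    data.frame(bin = levels(bin),
               lower = binEdges[-length(binEdges)],
               upper = binEdges[-1L],
               n = n, fraction = unname(frac), row.names = NULL)
}

#' RNA-protein concordance correlation
#'
#' Correlation between median TPM and median LFQ over matched gene /
#' protein pairs, restricted to proteins called in the secretome when
#' \code{calls} is supplied.
#'
#' @param tpmMedians named numeric vector of median TPM per gene.
#' @param lfqMedians named numeric vector of median LFQ per protein.
#' @param method \code{"spearman"} (default) or \code{"pearson"}.
#' @param calls optional data.frame from [callSecretome()] restricting the
#'   comparison to in-secretome proteins.
#' @return Correlation coefficient; fewer than 3 matched points is an
#'   error.
#' @export
rnaProteinCorrelation <- function(tpmMedians, lfqMedians,
                                  method = c("spearman", "pearson"),
                                  calls = NULL) {
    method <- match.arg(method)
    genes <- intersect(names(tpmMedians), names(lfqMedians))
    if (!is.null(calls))
        genes <- intersect(genes, calls$protein[calls$in_secretome])
    if (length(genes) < 3L)
        stop("fewer than 3 matched gene/protein pairs")
    stats::cor(tpmMedians[genes], lfqMedians[genes], method = method)
}
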