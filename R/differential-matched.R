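#' Derive patient-matched sample pairs
#'
#' Builds the matched-pair design for a compartment comparison of one cell
#' type: each patient with exactly one sample of the cell type in each
#' compartment contributes one pair (condition A = \code{condA}, condition
#' B = \code{condB}).
#'
#' @param x a \linkS4class{TpmExperiment}.
#' @param cellTypeSel cell type to compare (e.g. \code{"TU"}).
#' @param condA,condB compartment labels of conditions A and B (defaults
#'   omentum vs ascites).
#' @return data.frame with columns patient_id, sample_A, sample_B.
#' @export
matchedPairs <- function(x, cellTypeSel, condA = "omentum",
                         condB = "ascites") {
    ct <- cellType(x); comp <- sampleCompartment(x); pid <- patientId(x)
    sel <- ct == cellTypeSel
    pairs <- lapply(sort(unique(pid[sel])), function(p) {
        a <- names(ct)[sel & pid == p & comp == condA]
        b <- names(ct)[sel & pid == p & comp == condB]
        if (length(a) == 1L && length(b) == 1L)
            data.frame(patient_id = p, sample_A = a, sample_B = b)
        else NULL
    })
    out <- do.call(rbind, pairs)
    if (is.null(out))
        out <- data.frame(patient_id = character(), sample_A = character(),
                          sample_B = character())
    out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate q-values. Input p-values must lie in
#' (0, 1]; anything else is a hard error rather than silently propagated.
#'
#' @param p numeric vector of nominal p-values.
#' @return q-values in the input order.
#' @export
bhAdjust <- function(p) {
    if (!length(p)) return(numeric())
    if (any(is.na(p)) || any(p <= 0) || any(p > 1))
        stop("p-values must lie in (0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Patient-matched paired differential expression
#'
#' Per gene: a two-sided paired t-test on log2(TPM + 1) across the matched
#' pairs, a median-based fold change (condition A over B, additive offset
#' \code{fcOffset} guarding zero medians), and the calling rule: a gene is
#' called when the fold change exceeds \code{fc} in either direction
#' (strict), the larger of the two condition medians exceeds \code{tpm}
#' (strict), and the nominal p-value is below \code{alpha}. BH q-values are
#' reported alongside for transparency but do not drive the call. Pairs
#' with zero-variance differences get p = 1 and a flag.
#'
#' @param x a \linkS4class{TpmExperiment} (adjusted, renormalized).
#' @param pairs data.frame from [matchedPairs()] (>= 3 pairs required).
#' @param fc strict median fold-change threshold (default 3).
#' @param tpmMin strict TPM threshold on the larger condition median
#'   (default 3).
#' @param alpha nominal significance level (default 0.05).
#' @param fcOffset additive offset for the median fold change (default 0.1).
#' @param log2Offset additive offset inside the log2 transform (default 1).
#' @return data.frame: gene, median_A, median_B, fc, p, q, called,
#'   direction, zero_variance.
#' @export
pairedDE <- function(x, pairs, fc = 3, tpmMin = 3, alpha = 0.05,
                     fcOffset = 0.1, log2Offset = 1) {
    stopifnot(is(x, "TpmExperiment"))
    if (nrow(pairs) < 3L)
        stop("at least 3 matched pairs are required (got ", nrow(pairs), ")")
    m <- tpm(x)
    A <- m[, pairs$sample_A, drop = FALSE]
    B <- m[, pairs$sample_B, drop = FALSE]
    d <- log2(A + log2Offset) - log2(B + log2Offset)
    n <- ncol(d)
    dm <- rowMeans(d)
    ds <- apply(d, 1L, stats::sd)
    zeroVar <- ds == 0
    tstat <- ifelse(zeroVar, 0, dm / (ds / sqrt(n)))
    p <- ifelse(zeroVar, 1, 2 * stats::pt(-abs(tstat), df = n - 1L))
    medA <- apply(A, 1L, stats::median)
    medB <- apply(B, 1L, stats::median)
    fcVal <- (medA + fcOffset) / (medB + fcOffset)
    called <- (fcVal > fc | fcVal < 1 / fc) & pmax(medA, medB) > tpmMin &
        p < alpha
    data.frame(gene = rownames(m), median_A = medA, median_B = medB,
               fc = fcVal, p = p, q = bhAdjust(p), called = called,
               direction = ifelse(fcVal >= 1, "up", "down"),
               zero_variance = zeroVar, row.names = NULL)
}

#' Correlation between matched condition profiles
#'
#' Rank (Spearman) or linear (Pearson) correlation between the two
#' conditions' median expression profiles over all genes passing a minimal
#' expression filter (median > 0 in either condition).
#'
#' @param x a \linkS4class{TpmExperiment}.
#' @param pairs data.frame from [matchedPairs()].
#' @param method \code{"spearman"} (default) or \code{"pearson"}.
#' @return Correlation coefficient (NA with a warning when a profile is
#'   constant).
#' @export
matchedCorrelation <- function(x, pairs, method = c("spearman", "pearson")) {
    method <- match.arg(method)
    m <- tpm(x)
    medA <- apply(m[, pairs$sample_A, drop = FALSE], 1L, stats::median)
    medB <- apply(m[, pairs$sample_B, drop = FALSE], 1L, stats::median)
    keep <- medA > 0 | medB > 0
    if (sum(keep) < 2L)
        stop("fewer than 2 genes pass the expression filter")
    a <- medA[keep]; b <- medB[keep]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        warning("constant profile: correlation undefined")
        return(NA_real_)
    }
    stats::cor(a, b, method = method)
}

#' Read a gene-level survival-statistics table
#'
#' TSV with columns \code{gene}, \code{rfs_p} (relapse-free-survival
#' p-value), \code{rfs_hr} (hazard ratio) and \code{os_z} (overall-survival
#' z-score). The package ships the published 32-gene stroma-selective table
#' as \code{system.file("extdata", "stroma_survival_stats.tsv",
#' package = "TMEnet")}.
#'
#' @param path TSV path.
#' @return data.frame validated against the column contract.
#' @export
readSurvivalStats <- function(path) {
    tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("gene", "rfs_p", "rfs_hr", "os_z")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
        stop("survival table lacks column(s): ", paste(miss, collapse = ", "))
    if (any(tab$rfs_p <= 0 | tab$rfs_p > 1))
        stop("rfs_p must lie in (0, 1]")
    if (any(tab$rfs_hr <= 0))
        stop("rfs_hr must be positive")
    tab
}

#' Dual-significance survival filter
#'
#' Keeps genes significant for both relapse-free survival (RFS p-value <
#' \code{pMax}) and overall survival (|z| > \code{zAbsMin}; |z| = 1.96
#' corresponds to p = .05) and labels the direction: "short survival" when
#' the hazard ratio exceeds 1 and z > 0, "long survival" when both point
#' the other way, "discordant" otherwise.
#'
#' @param table data.frame from [readSurvivalStats()].
#' @param pMax RFS p-value threshold (default 0.05, strict).
#' @param zAbsMin absolute OS z-score threshold (default 1.96, strict).
#' @return The filtered rows with an added \code{direction} column.
#' @export
survivalFilter <- function(table, pMax = 0.05, zAbsMin = 1.96) {
    keep <- table$rfs_p < pMax & abs(table$os_z) > zAbsMin
    out <- table[keep, , drop = FALSE]
    out$direction <- ifelse(out$rfs_hr > 1 & out$os_z > 0, "short survival",
                     ifelse(out$rfs_hr < 1 & out$os_z < 0, "long survival",
                            "discordant"))
    rownames(out) <- NULL
    out
}
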