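#' Default cell type to compartment-group mapping
#'
#' Tumour cells form the tumour group, macrophages and T cells the immune
#' group, and adipocytes, mesothelial cells and fibroblasts the (omental)
#' stroma group.
#'
#' @return Named character vector cell type -> group.
#' @export
defaultGrouping <- function() {
    c(TU = "tumour", TAM = "immune", TAT = "immune",
      ADI = "stroma", MESO = "stroma", CAF = "stroma")
}

#' Call expressed genes per cell type
#'
#' A gene counts as expressed in a cell type when its median TPM across that
#' cell type's samples is strictly greater than \code{tpmThreshold}
#' (default 2 TPM).
#'
#' @param x a \linkS4class{TpmExperiment} (adjusted).
#' @param tpmThreshold strict median TPM threshold (default 2).
#' @param preferCompartment compartment preference passed to
#'   [cellTypeMedians()] (default \code{"omentum"}).
#' @param genes optional gene subset (e.g. a cytokine / growth-factor list).
#' @return A list with \code{expressed} (logical gene x cell-type matrix)
#'   and \code{medians} (the underlying median matrix).
#' @export
callExpressed <- function(x, tpmThreshold = 2, preferCompartment = "omentum",
                          genes = NULL) {
    med <- cellTypeMedians(x, preferCompartment, genes)
    list(expressed = med > tpmThreshold, medians = med)
}

## Cell types inside `group` whose median beats fc x the best median outside
## the group; used both for group selectivity and Venn membership.
.membersAbove <- function(med, group, fc) {
    outside <- setdiff(colnames(med), group)
    baseline <- if (length(outside))
        apply(med[, outside, drop = FALSE], 1L, max) else 0
    med[, group, drop = FALSE] > fc * baseline
}

#' Classify cell-type / compartment selectivity
#'
#' Partitions expressed genes by where their expression is concentrated. A
#' gene is selective for a group (tumour, or the host groups stroma /
#' immune) when the median of the group's top-expressing cell type is more
#' than \code{fc}-fold (strict) above the maximum median of all cell types
#' outside the group — the strictest reading of a fold-change cut against
#' "all other cell types". Within a selective group, the member cell types
#' are those whose own median beats \code{fc}-fold the best median outside
#' the group, yielding the Venn-style shared / single-type accounting.
#'
#' @param x a \linkS4class{TpmExperiment} (adjusted).
#' @param grouping named vector cell type -> group label
#'   (default [defaultGrouping()]).
#' @param fc strict fold-change threshold (default 5).
#' @param tpmThreshold strict expression threshold (default 2 TPM).
#' @param preferCompartment compartment preference (default omentum).
#' @param genes optional gene subset.
#' @return A list with \code{calls} (data.frame: gene, category,
#'   expressed_in, selective_for — sets collapsed with ";"), \code{counts}
#'   (named partition counts: expressed, tumour, host, host_stroma,
#'   host_immune, host_shared, shared, plus stroma-subset counts) and
#'   \code{medians}.
#' @export
classifySelectivity <- function(x, grouping = defaultGrouping(), fc = 5,
                                tpmThreshold = 2,
                                preferCompartment = "omentum", genes = NULL) {
    ce <- callExpressed(x, tpmThreshold, preferCompartment, genes)
    med <- ce$medians
    expressedAnywhere <- rowSums(ce$expressed) > 0
    med <- med[expressedAnywhere, , drop = FALSE]
    expr <- ce$expressed[expressedAnywhere, , drop = FALSE]
    types <- colnames(med)
    grouping <- grouping[types]

    tumourTypes <- types[grouping == "tumour"]
    immuneTypes <- types[grouping == "immune"]
    stromaTypes <- types[grouping == "stroma"]
    hostTypes <- c(immuneTypes, stromaTypes)

    gmax <- function(g) if (length(g))
        apply(med[, g, drop = FALSE], 1L, max) else rep(0, nrow(med))
    tumourMax <- gmax(tumourTypes)
    immuneMax <- gmax(immuneTypes)
    stromaMax <- gmax(stromaTypes)
    hostMax <- pmax(immuneMax, stromaMax)

    tumourSel <- tumourMax > fc * hostMax
    hostSel <- hostMax > fc * tumourMax
    category <- ifelse(tumourSel, "tumour",
                ifelse(hostSel,
                       ifelse(stromaMax > fc * immuneMax, "host_stroma",
                       ifelse(immuneMax > fc * stromaMax, "host_immune",
                              "host_shared")),
                       "shared"))

    selFor <- character(nrow(med))
    memTumour <- .membersAbove(med, tumourTypes, fc)
    memHost <- .membersAbove(med, hostTypes, fc)
    for (i in seq_len(nrow(med))) {
        sel <- switch(category[i],
            tumour = tumourTypes[memTumour[i, ]],
            host_stroma = , host_immune = , host_shared =
                hostTypes[memHost[i, ]],
            character())
        selFor[i] <- paste(sel, collapse = ";")
    }
    exprIn <- apply(expr, 1L, function(e) paste(types[e], collapse = ";"))

    stromaGenes <- category == "host_stroma"
    memStroma <- .membersAbove(med, stromaTypes, fc)[stromaGenes, ,
                                                     drop = FALSE]
    stromaSubset <- apply(memStroma, 1L,
                          function(e) paste(stromaTypes[e], collapse = ";"))
    counts <- c(expressed = nrow(med),
                tumour = sum(category == "tumour"),
                host = sum(category %in%
                           c("host_stroma", "host_immune", "host_shared")),
                host_stroma = sum(category == "host_stroma"),
                host_immune = sum(category == "host_immune"),
                host_shared = sum(category == "host_shared"),
                shared = sum(category == "shared"))
    subsetCounts <- table(factor(stromaSubset))

    list(calls = data.frame(gene = rownames(med), category = category,
                            expressed_in = exprIn, selective_for = selFor,
                            row.names = NULL),
         counts = counts,
         stromaSubsets = subsetCounts,
         medians = med)
}

#' Ligand -> target-cell receptor scores
#'
#' Summarizes where a ligand's receptors are expressed, in three steps:
#' (i) each receptor gene's median TPM is normalized across cell types by
#' its maximum; (ii) the normalized values of all receptors of a ligand are
#' summed per cell type; (iii) each ligand's sums are normalized by their
#' maximum across cell types, yielding scores in [0, 1] with the
#' top-receiving cell type at 1. Step (i) makes the score invariant to
#' uniform rescaling of any receptor's expression.
#'
#' @param map a \linkS4class{LigandReceptorMap}.
#' @param x a \linkS4class{TpmExperiment} (adjusted).
#' @param preferCompartment compartment preference (default omentum).
#' @return Numeric ligand x cell-type matrix in [0, 1]. Ligands whose
#'   receptors are all absent or unexpressed get a zero row with a warning;
#'   receptors absent from the matrix are dropped with a warning.
#' @export
receptorTargetScores <- function(map, x, preferCompartment = "omentum") {
    stopifnot(is(map, "LigandReceptorMap"), is(x, "TpmExperiment"))
    tab <- lrTable(map)
    receptors <- unique(tab$receptor)
    present <- receptors[receptors %in% rownames(x)]
    absent <- setdiff(receptors, present)
    if (length(absent))
        warning("receptor gene(s) absent from matrix dropped: ",
                paste(utils::head(absent, 10L), collapse = ", "))
    med <- cellTypeMedians(x, preferCompartment, present)
    rmax <- apply(med, 1L, max)
    norm <- med / ifelse(rmax > 0, rmax, 1)  # zero rows stay zero

    lig <- unique(tab$ligand)
    scores <- matrix(0, nrow = length(lig), ncol = ncol(med),
                     dimnames = list(lig, colnames(med)))
    for (l in lig) {
        rec <- intersect(unique(tab$receptor[tab$ligand == l]), present)
        if (!length(rec)) {
            warning("ligand '", l, "' has no receptor in the matrix; ",
                    "scores set to 0")
            next
        }
        sums <- colSums(norm[rec, , drop = FALSE])
        mx <- max(sums)
        if (mx > 0) scores[l, ] <- sums / mx
        else warning("no receptor of ligand '", l,
                     "' is expressed; scores set to 0")
    }
    scores
}

#' Assemble the metastasis-associated signalling network
#'
#' Emits edges producer cell type -> ligand -> target cell type for
#' metastasis-flagged ligands: the ligand must be expressed by at least one
#' cell type, and the target cell type must express at least one cognate
#' receptor at a median above \code{receptorTpm} (strict). Producer cell
#' types are the ligand's selective cell types when it is selective, its
#' expressing cell types otherwise. Each edge carries the ligand's
#' receptor target score for the target cell type.
#'
#' @param selectivity result of [classifySelectivity()] computed on the
#'   relevant gene set.
#' @param map a \linkS4class{LigandReceptorMap} with metastasis flags.
#' @param x a \linkS4class{TpmExperiment} (adjusted).
#' @param receptorTpm strict receptor median TPM threshold (default 2).
#' @param targetCellTypes restrict target cell types (default: all).
#' @param preferCompartment compartment preference (default omentum).
#' @return data.frame with columns source_cell_type, ligand,
#'   target_cell_type, receptor_score.
#' @export
buildMetastasisNetwork <- function(selectivity, map, x, receptorTpm = 2,
                                   targetCellTypes = NULL,
                                   preferCompartment = "omentum") {
    stopifnot(is(map, "LigandReceptorMap"))
    tab <- lrTable(map)
    flagged <- unique(tab$ligand[tab$metastasis])
    calls <- selectivity$calls
    present <- unique(tab$receptor[tab$receptor %in% rownames(x)])
    recMed <- if (length(present))
        cellTypeMedians(x, preferCompartment, present) else NULL
    scores <- suppressWarnings(
        receptorTargetScores(map, x, preferCompartment))
    if (is.null(targetCellTypes))
        targetCellTypes <- colnames(scores)

    edges <- list()
    for (l in flagged) {
        row <- calls[calls$gene == l, , drop = FALSE]
        if (!nrow(row)) next  # not expressed anywhere
        producers <- strsplit(row$selective_for, ";", fixed = TRUE)[[1L]]
        if (!length(producers) || !nzchar(producers[1L]))
            producers <- strsplit(row$expressed_in, ";", fixed = TRUE)[[1L]]
        producers <- producers[nzchar(producers)]
        if (!length(producers)) next
        rec <- intersect(unique(tab$receptor[tab$ligand == l]), present)
        if (!length(rec)) next
        for (tgt in targetCellTypes) {
            if (!any(recMed[rec, tgt] > receptorTpm)) next
            for (p in producers)
                edges[[length(edges) + 1L]] <- data.frame(
                    source_cell_type = p, ligand = l,
                    target_cell_type = tgt,
                    receptor_score = scores[l, tgt])
        }
    }
    if (!length(edges))
        return(data.frame(source_cell_type = character(),
                          ligand = character(),
                          target_cell_type = character(),
                          receptor_score = numeric()))
    do.call(rbind, edges)
}

#' Read a ligand-receptor annotation table
#'
#' TSV with columns \code{ligand}, \code{receptor} and optionally
#' \code{metastasis} (logical; defaults to FALSE when absent).
#'
#' @param path TSV path.
#' @return A \linkS4class{LigandReceptorMap}.
#' @export
readLigandReceptorMap <- function(path) {
    tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    need <- c("ligand", "receptor")
    miss <- setdiff(need, colnames(tab))
    if (length(miss))
        stop("ligand-receptor table lacks column(s): ",
             paste(miss, collapse = ", "))
    flags <- if ("metastasis" %in% colnames(tab))
        as.logical(tab$metastasis) else FALSE
    LigandReceptorMap(tab$ligand, tab$receptor, flags)
}

#' Write network edges as node/edge TSV pair
#'
#' @param edges data.frame from [buildMetastasisNetwork()].
#' @param edgePath output TSV for edges.
#' @param nodePath optional output TSV for the node list.
#' @return Invisibly, \code{edgePath}.
#' @export
writeNetwork <- function(edges, edgePath, nodePath = NULL) {
    utils::write.table(edges, edgePath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(nodePath)) {
        nodes <- unique(data.frame(
            node = c(edges$source_cell_type, edges$ligand,
                     edges$target_cell_type),
            kind = rep(c("cell_type", "ligand", "cell_type"),
                       each = nrow(edges))))
        utils::write.table(nodes, nodePath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(edgePath)
}
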