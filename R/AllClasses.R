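#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' MicrobiomeExperiment: genus-level abundances with labels and genomic vectors
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single `"abundance"` assay with genera in rows and samples in columns
#' (values in percent units after [normalizeToPercent()]), binary phenotype
#' labels in `colData(x)$label` (1 = disease, 0 = control), and a fixed-width
#' per-genus genomic embedding matrix in `rowData(x)$embedding`.
#'
#' Note the transposition relative to the on-disk layout: files store samples
#' in rows (see [loadDataset()]); in memory genera are features and therefore
#' rows, following Bioconductor convention.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [MicrobiomeExperiment()], [abundances()], [sampleLabels()],
#'   [genomicVectors()]
#' @export
setClass("MicrobiomeExperiment", contains = "SummarizedExperiment")

setValidity("MicrobiomeExperiment", function(object) {
    msg <- character()
    if (!"abundance" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'abundance' is required")
    else {
        a <- SummarizedExperiment::assay(object, "abundance")
        if (!is.numeric(a) || anyNA(a) || any(!is.finite(a)))
            msg <- c(msg, "abundance values must be finite numbers")
        else if (any(a < 0))
            msg <- c(msg, "abundance values must be non-negative")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "genus identifiers (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers (colnames) must be present and unique")
    if ("label" %in% colnames(SummarizedExperiment::colData(object))) {
        lab <- SummarizedExperiment::colData(object)$label
        if (anyNA(lab) || !all(lab %in% c(0L, 1L)))
            msg <- c(msg, "labels must be 0 (control) or 1 (disease) for every sample")
    }
    if ("embedding" %in% colnames(SummarizedExperiment::rowData(object))) {
        emb <- SummarizedExperiment::rowData(object)$embedding
        if (!is.matrix(emb) || !is.numeric(emb) || any(!is.finite(emb)))
            msg <- c(msg, "rowData embedding must be a finite numeric matrix")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a MicrobiomeExperiment
#'
#' @param abundance numeric matrix, samples in rows and genera in columns
#'   (the canonical on-disk orientation); transposed internally.
#' @param labels named vector (0/1) covering exactly the sample ids, or NULL.
#' @param embeddings numeric matrix with one row per genus (rownames = genus
#'   ids), or NULL. Genera of `abundance` missing from `embeddings` are
#'   dropped with a warning; extra embedding rows are ignored.
#' @return A [MicrobiomeExperiment-class] object.
#' @examples
#' toy <- makeToyFixture()
#' dim(toy)                 # genera x samples
#' colSums(abundances(toy)) # each 100
#' @export
MicrobiomeExperiment <- function(abundance, labels = NULL, embeddings = NULL) {
    if (is.data.frame(abundance)) abundance <- as.matrix(abundance)
    stopifnot(is.matrix(abundance))
    if (is.null(rownames(abundance)) || is.null(colnames(abundance)))
        stop("abundance matrix needs sample rownames and genus colnames")
    dup <- rownames(abundance)[duplicated(rownames(abundance))]
    if (length(dup)) stop("duplicate sample identifier: ", dup[[1L]])
    dup <- colnames(abundance)[duplicated(colnames(abundance))]
    if (length(dup)) stop("duplicate genus identifier: ", dup[[1L]])

    a <- t(abundance)  # genera x samples
    rd <- S4Vectors::DataFrame(row.names = rownames(a))
    if (!is.null(embeddings)) {
        if (is.null(rownames(embeddings)))
            stop("embeddings matrix needs genus rownames")
        dup <- rownames(embeddings)[duplicated(rownames(embeddings))]
        if (length(dup)) stop("duplicate genus identifier in embeddings: ", dup[[1L]])
        missing <- setdiff(rownames(a), rownames(embeddings))
        if (length(missing)) {
            warning(sprintf(
                "dropping %d genus/genera without genomic vectors: %s",
                length(missing), paste(missing, collapse = ", ")))
            a <- a[setdiff(rownames(a), missing), , drop = FALSE]
        }
        emb <- as.matrix(embeddings)[rownames(a), , drop = FALSE]
        storage.mode(emb) <- "double"
        rd <- S4Vectors::DataFrame(row.names = rownames(a))
        rd$embedding <- emb
    }
    cd <- S4Vectors::DataFrame(row.names = colnames(a))
    if (!is.null(labels)) {
        if (is.null(names(labels))) stop("labels must be named by sample id")
        missing <- setdiff(colnames(a), names(labels))
        if (length(missing))
            stop("label missing for sample: ", paste(missing, collapse = ", "))
        bad <- names(labels)[!labels %in% c(0, 1)]
        if (length(bad))
            stop("label outside {0,1} for sample: ", paste(bad, collapse = ", "))
        cd$label <- as.integer(labels[colnames(a)])
    }
    new("MicrobiomeExperiment", SummarizedExperiment::SummarizedExperiment(
        assays = list(abundance = a), rowData = rd, colData = cd))
}

#' Global microbial co-expression network
#'
#' An undirected genus graph. Each edge carries the mean COAT (CLR-Pearson)
#' correlation across stability-selection subsamples; only pairs whose
#' correlation magnitude reached `tau` with a consistent sign in every
#' subsample are retained.
#'
#' @slot genera character vector of node identifiers.
#' @slot edges data.frame with columns `from`, `to` (genus ids, `from < to`
#'   in `genera` order) and `weight` (mean correlation, in \[-1, 1\]).
#' @slot tau correlation magnitude threshold.
#' @slot nSubsamples number of stability-selection draws.
#' @slot subsampleFraction fraction of samples per draw.
#' @slot pseudocount value substituted into zero cells before the CLR.
#' @slot seed integer seed that fixed the subsample draws.
#' @export
setClass("CoexpressionNetwork", representation(
    genera = "character", edges = "data.frame", tau = "numeric",
    nSubsamples = "integer", subsampleFraction = "numeric",
    pseudocount = "numeric", seed = "integer"))

setValidity("CoexpressionNetwork", function(object) {
    msg <- character()
    e <- object@edges
    if (!all(c("from", "to", "weight") %in% colnames(e)))
        msg <- c(msg, "edges need columns from, to, weight")
    else if (nrow(e)) {
        if (!all(e$from %in% object@genera) || !all(e$to %in% object@genera))
            msg <- c(msg, "edge endpoints must be network genera")
        if (any(e$from == e$to)) msg <- c(msg, "self-loops are not allowed")
        key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
        if (anyDuplicated(key)) msg <- c(msg, "duplicate undirected edge")
        if (any(abs(e$weight) > 1 + 1e-12)) msg <- c(msg, "weights must lie in [-1, 1]")
        if (any(abs(e$weight) < object@tau - 1e-12))
            msg <- c(msg, "every retained edge must satisfy |weight| >= tau")
    }
    if (anyDuplicated(object@genera)) msg <- c(msg, "duplicate genus")
    if (length(msg)) msg else TRUE
})

#' Sample-specific induced subgraph
#'
#' The global network restricted to the genera with non-zero abundance in one
#' sample, carrying per-node abundance scalars and genomic vectors.
#'
#' @slot sampleId sample identifier.
#' @slot genera active genus ids (non-zero abundance), in network order.
#' @slot abundance percent abundances, parallel to `genera`.
#' @slot genomic matrix of genomic vectors, one row per active genus.
#' @slot edges integer matrix with two columns: 1-based indices into
#'   `genera`, first column < second column; zero rows allowed.
#' @export
setClass("SampleGraph", representation(
    sampleId = "character", genera = "character", abundance = "numeric",
    genomic = "matrix", edges = "matrix"))

setValidity("SampleGraph", function(object) {
    msg <- character()
    n <- length(object@genera)
    if (n == 0L) msg <- c(msg, "a sample graph needs at least one active node")
    if (length(object@abundance) != n || nrow(object@genomic) != n)
        msg <- c(msg, "abundance/genomic must align with genera")
    if (any(object@abundance <= 0)) msg <- c(msg, "active nodes must have positive abundance")
    e <- object@edges
    if (ncol(e) != 2L) msg <- c(msg, "edges must have two columns")
    else if (nrow(e)) {
        if (any(e < 1L) || any(e > n)) msg <- c(msg, "edge endpoint outside the active node set")
        if (any(e[, 1L] >= e[, 2L])) msg <- c(msg, "edges must satisfy from < to")
    }
    if (length(msg)) msg else TRUE
})

#' Graph attention classifier state
#'
#' Holds the architecture configuration (see [modelConfig()]) and all
#' learnable parameters: the shared 64-dimensional abundance basis vector,
#' per-layer per-head GATv2 transforms and attention vectors, the readout
#' projection, and the MLP head. Parameters are plain numeric matrices keyed
#' by name, so a model round-trips exactly through [saveModel()] /
#' [readModel()].
#'
#' @slot config list produced by [modelConfig()].
#' @slot params named list of numeric vectors/matrices.
#' @export
setClass("GATModel", representation(config = "list", params = "list"))

#' Per-sample attention profile
#'
#' @slot sampleId sample identifier.
#' @slot attention named numeric vector on the simplex (sums to 1) over the
#'   sample's active genera.
#' @slot clr CLR-transformed attention (sums to 0).
#' @export
setClass("AttentionProfile", representation(
    sampleId = "character", attention = "numeric", clr = "numeric"))

setValidity("AttentionProfile", function(object) {
    msg <- character()
    if (abs(sum(object@attention) - 1) > 1e-6)
        msg <- c(msg, "attention must sum to 1")
    if (any(object@attention <= 0)) msg <- c(msg, "attention must be positive")
    if (abs(sum(object@clr)) > 1e-6) msg <- c(msg, "CLR attention must sum to 0")
    if (length(msg)) msg else TRUE
})
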