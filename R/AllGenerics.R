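#' Accessors for microGAT objects
#'
#' `abundances()` returns the genus x sample percent-abundance matrix;
#' `sampleLabels()` the named 0/1 phenotype vector; `genomicVectors()` the
#' genus x d_g genomic embedding matrix; `networkEdges()` the edge table of a
#' [CoexpressionNetwork-class]; `networkGenera()` its node set;
#' `activeGenera()` the non-zero genera of a [SampleGraph-class].
#'
#' @param x a microGAT object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))
#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))
#' @rdname accessors
#' @export
setGeneric("genomicVectors", function(x) standardGeneric("genomicVectors"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("networkGenera", function(x) standardGeneric("networkGenera"))
#' @rdname accessors
#' @export
setGeneric("activeGenera", function(x) standardGeneric("activeGenera"))

#' @rdname accessors
setMethod("abundances", "MicrobiomeExperiment", function(x)
    SummarizedExperiment::assay(x, "abundance"))

#' @rdname accessors
setMethod("sampleLabels", "MicrobiomeExperiment", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if (!"label" %in% colnames(cd)) return(NULL)
    stats::setNames(as.integer(cd$label), colnames(x))
})

#' @rdname accessors
setMethod("genomicVectors", "MicrobiomeExperiment", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    if (!"embedding" %in% colnames(rd)) return(NULL)
    emb <- rd$embedding
    rownames(emb) <- rownames(x)
    emb
})

#' @rdname accessors
setMethod("networkEdges", "CoexpressionNetwork", function(x) x@edges)
#' @rdname accessors
setMethod("networkGenera", "CoexpressionNetwork", function(x) x@genera)
#' @rdname accessors
setMethod("activeGenera", "SampleGraph", function(x) x@genera)

setMethod("show", "MicrobiomeExperiment", function(object) {
    lab <- sampleLabels(object)
    cat(sprintf("MicrobiomeExperiment: %d genera x %d samples\n",
                nrow(object), ncol(object)))
    if (!is.null(lab))
        cat(sprintf("  labels: %d disease / %d control\n",
                    sum(lab == 1L), sum(lab == 0L)))
    emb <- genomicVectors(object)
    if (!is.null(emb))
        cat(sprintf("  genomic vectors: %d-dimensional\n", ncol(emb)))
})

setMethod("show", "CoexpressionNetwork", function(object) {
    cat(sprintf(
        "CoexpressionNetwork: %d genera, %d edges (|c| >= %g, %dx%.0f%% subsamples, seed %d)\n",
        length(object@genera), nrow(object@edges), object@tau,
        object@nSubsamples, 100 * object@subsampleFraction, object@seed))
})

setMethod("show", "SampleGraph", function(object) {
    cat(sprintf("SampleGraph '%s': %d active genera, %d edges\n",
                object@sampleId, length(object@genera), nrow(object@edges)))
})

setMethod("show", "GATModel", function(object) {
    cfg <- object@config
    cat(sprintf(
        "GATModel: %d GATv2 layers x %d heads (F = %d), abundance basis %d, genomic dim %d\n",
        cfg$n_layers, cfg$n_heads, cfg$per_head_dim, cfg$abundance_dim,
        cfg$genomic_dim))
    cat(sprintf("  parameters: %d values\n",
                length(unlist(object@params))))
})

setMethod("show", "AttentionProfile", function(object) {
    cat(sprintf("AttentionProfile '%s' over %d genera (top: %s)\n",
                object@sampleId, length(object@attention),
                names(sort(object@attention, decreasing = TRUE))[1L]))
})
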