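#' Architecture configuration for the graph attention classifier
#'
#' Defaults give the full-scale architecture: three stacked GATv2 layers
#' with eight heads of width 32 (concatenated width 256 in intermediate
#' layers, head-averaged width 32 after the final layer), a shared learnable
#' 64-dimensional abundance basis, 768-dimensional genomic vectors, 0.3 edge
#' and node dropout, Mish activations, LeakyReLU slope 0.2 inside the
#' attention, and a two-hidden-layer MLP head (32, 16) with sigmoid output.
#'
#' @param n_layers number of GATv2 layers (L).
#' @param n_heads attention heads per layer (K).
#' @param per_head_dim per-head output width (F); intermediate layers emit
#'   `n_heads * per_head_dim`, the final layer averages heads to
#'   `per_head_dim`.
#' @param abundance_dim width of the shared learnable abundance basis.
#' @param genomic_dim width of the genomic vectors (0 disables them).
#' @param edge_dropout,node_dropout training-time dropout probabilities.
#' @param mlp_hidden widths of the two MLP hidden layers.
#' @param leaky_slope LeakyReLU negative slope inside the attention score.
#' @return a validated list of class `model_config`.
#' @export
modelConfig <- function(n_layers = 3L, n_heads = 8L, per_head_dim = 32L,
                        abundance_dim = 64L, genomic_dim = 768L,
                        edge_dropout = 0.3, node_dropout = 0.3,
                        mlp_hidden = c(32L, 16L), leaky_slope = 0.2) {
    cfg <- list(n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
                per_head_dim = as.integer(per_head_dim),
                abundance_dim = as.integer(abundance_dim),
                genomic_dim = as.integer(genomic_dim),
                edge_dropout = edge_dropout, node_dropout = node_dropout,
                mlp_hidden = as.integer(mlp_hidden),
                leaky_slope = leaky_slope)
    if (cfg$n_layers < 1L || cfg$n_heads < 1L || cfg$per_head_dim < 1L ||
        cfg$abundance_dim < 1L || cfg$genomic_dim < 0L ||
        any(cfg$mlp_hidden < 1L))
        stop("all dimensions must be positive (genomic_dim may be 0)")
    if (cfg$edge_dropout < 0 || cfg$edge_dropout >= 1 ||
        cfg$node_dropout < 0 || cfg$node_dropout >= 1)
        stop("dropout probabilities must lie in [0, 1)")
    class(cfg) <- "model_config"
    cfg
}

.glorot <- function(nin, nout) {
    lim <- sqrt(6 / (nin + nout))
    matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize a graph attention classifier
#'
#' All parameters are drawn from seeded uniform distributions (Glorot limits
#' for the transforms; the shared abundance basis from U(-0.3, 0.3)).
#'
#' @param config a [modelConfig()].
#' @param seed integer seed; same seed, identical model.
#' @return a [GATModel-class].
#' @export
initModel <- function(config, seed) {
    stopifnot(inherits(config, "model_config"))
    if (missing(seed)) stop("seed is mandatory")
    withr::with_seed(as.integer(seed), {
        K <- config$n_heads; Fd <- config$per_head_dim; KF <- K * Fd
        d0 <- config$abundance_dim + config$genomic_dim
        din <- c(d0, rep(KF, config$n_layers - 1L))
        params <- list(
            basis = stats::runif(config$abundance_dim, -0.3, 0.3),
            Wl = lapply(din, function(d) .glorot(d, KF)),
            Wr = lapply(din, function(d) .glorot(d, KF)),
            att = lapply(seq_len(config$n_layers), function(l) {
                lim <- sqrt(6 / (Fd + 1))
                stats::runif(KF, -lim, lim)
            }),
            Wp = stats::runif(Fd, -sqrt(6 / (Fd + 1)), sqrt(6 / (Fd + 1))),
            mlpW = NULL, mlpb = NULL)
        dims <- c(Fd, config$mlp_hidden, 1L)
        params$mlpW <- lapply(seq_len(length(dims) - 1L), function(j)
            .glorot(dims[j], dims[j + 1L]))
        params$mlpb <- lapply(seq_len(length(dims) - 1L), function(j)
            numeric(dims[j + 1L]))
        new("GATModel", config = unclass(config), params = params)
    })
}

## SampleGraph -> plain list consumed by the C++ core
.graphPayload <- function(graph, genomicDim) {
    g <- list(abund = graph@abundance,
              edges = graph@edges)
    if (genomicDim > 0L) {
        if (ncol(graph@genomic) != genomicDim)
            stop("graph genomic dimension ", ncol(graph@genomic),
                 " does not match model genomic_dim ", genomicDim)
        g$genomic_t <- unname(t(graph@genomic))
    } else g$genomic_t <- matrix(0, 0L, length(graph@abundance))
    g
}

#' Full forward pass of the classifier on one sample graph
#'
#' Evaluation-mode forward pass (no dropout, deterministic). Returns the
#' predicted probability together with the readout internals: the node
#' attention scores `A_i` (softmax over active nodes, summing to 1), the
#' scalar importance projections, the pooled graph embedding and the final
#' node embeddings.
#'
#' @param model a [GATModel-class].
#' @param graph a [SampleGraph-class].
#' @return list with `prob`, `attention` (named), `importance` (named),
#'   `pooled`, `node_embed`.
#' @export
gatForward <- function(model, graph) {
    stopifnot(is(model, "GATModel"), is(graph, "SampleGraph"))
    out <- .gatForwardCpp(model@params, model@config,
                          .graphPayload(graph, model@config$genomic_dim))
    names(out$attention) <- graph@genera
    names(out$importance) <- graph@genera
    rownames(out$node_embed) <- graph@genera
    out
}

#' Predict the disease probability for sample graphs
#'
#' Deterministic evaluation-mode prediction; invariant to node relabeling
#' and edge ordering.
#'
#' @param model a [GATModel-class].
#' @param graphs a [SampleGraph-class] or a list of them.
#' @return numeric probability vector in (0, 1).
#' @export
predictProb <- function(model, graphs) {
    if (is(graphs, "SampleGraph")) graphs <- list(graphs)
    vapply(graphs, function(g) gatForward(model, g)$prob, numeric(1L))
}

#' Average the predicted probabilities of an ensemble
#'
#' @param models list of [GATModel-class] objects with identical
#'   configurations (e.g. trained under different seeds).
#' @param graphs a [SampleGraph-class] or a list of them.
#' @return numeric vector: arithmetic mean of the member probabilities.
#' @export
ensemblePredict <- function(models, graphs) {
    if (is(models, "GATModel")) models <- list(models)
    if (!length(models)) stop("need at least one model")
    cfg0 <- models[[1L]]@config
    for (m in models)
        if (!identical(m@config, cfg0))
            stop("ensemble members must share an identical configuration")
    p <- vapply(models, function(m) predictProb(m, graphs),
                numeric(if (is(graphs, "SampleGraph")) 1L else length(graphs)))
    if (is.null(dim(p))) mean(p) else rowMeans(p)
}

#' Serialize / restore a model
#'
#' `saveModel()` writes the parameter map plus its configuration to a single
#' RDS file and, optionally, a JSON sidecar describing the configuration.
#' The round-trip is bit-identical.
#'
#' @param model a [GATModel-class].
#' @param path checkpoint path.
#' @param configPath optional JSON sidecar path.
#' @return `readModel()` returns the restored [GATModel-class].
#' @export
saveModel <- function(model, path, configPath = NULL) {
    saveRDS(list(config = model@config, params = model@params), path)
    if (!is.null(configPath))
        jsonlite::write_json(model@config, configPath, auto_unbox = TRUE,
                             digits = NA, pretty = TRUE)
    invisible(path)
}

#' @rdname saveModel
#' @export
readModel <- function(path) {
    x <- readRDS(path)
    new("GATModel", config = x$config, params = x$params)
}
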