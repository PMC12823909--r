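#' Ablation protocols: remove genomic vectors, shuffle co-expression edges
#'
#' Trains and evaluates seed ensembles under three variants:
#' \describe{
#'   \item{full}{the intact model.}
#'   \item{no_genomic}{genomic vectors removed from the node features (the
#'     layer-0 width shrinks to the abundance basis width); graph topology
#'     untouched.}
#'   \item{shuffled_edges}{additionally rewires each sample graph uniformly
#'     at random, preserving node set and edge count (per-sample seeds
#'     derived from the run seed).}
#' }
#' Per-seed AUROCs of each ablated variant are compared against `full`
#' with the Mann-Whitney U test.
#'
#' @param experiment a [MicrobiomeExperiment-class] with labels.
#' @param network a [CoexpressionNetwork-class].
#' @param variants subset of `c("full", "no_genomic", "shuffled_edges")`.
#' @param modelConfig a [modelConfig()] (the intact configuration).
#' @param trainConfig a [trainConfig()].
#' @param split a [splitDataset()] result.
#' @param seed base seed; run seeds are `seed + 0:(n_ensemble_seeds-1)`.
#' @return list per variant with `report` (see [metricsReport()]) and
#'   `probs` (test-sample x seed matrix), plus a `comparisons` data.frame of
#'   Mann-Whitney tests of per-seed AUROC against `full` when present.
#' @export
runAblation <- function(experiment, network,
                        variants = c("full", "no_genomic", "shuffled_edges"),
                        modelConfig, trainConfig, split, seed) {
    variants <- match.arg(variants, several.ok = TRUE)
    if (missing(seed)) stop("seed is mandatory")
    labels <- sampleLabels(experiment)
    graphs <- sampleGraphs(network, experiment)
    out <- list()
    for (v in variants) {
        mc <- modelConfig
        gs <- graphs
        if (v %in% c("no_genomic", "shuffled_edges"))
            mc$genomic_dim <- 0L
        if (v == "shuffled_edges")
            gs <- stats::setNames(lapply(seq_along(graphs), function(i)
                shuffleEdges(graphs[[i]], seed = as.integer(seed) + 1000L + i)),
                names(graphs))
        models <- trainEnsemble(gs, labels, split, mc, trainConfig,
                                seed = seed)
        test_g <- gs[split$test]
        probs <- vapply(models, function(m) predictProb(m, test_g),
                        numeric(length(split$test)))
        rownames(probs) <- split$test
        out[[v]] <- list(report = metricsReport(probs, labels[split$test]),
                         probs = probs)
    }
    if ("full" %in% variants && length(variants) > 1L) {
        ref <- out$full$report$per_seed$auroc
        out$comparisons <- do.call(rbind, lapply(
            setdiff(variants, "full"), function(v) {
                mw <- mannWhitneyU(out[[v]]$report$per_seed$auroc, ref)
                data.frame(variant = v, U = mw$U, p = mw$p,
                           mean_auroc = mean(out[[v]]$report$per_seed$auroc),
                           full_mean_auroc = mean(ref))
            }))
    }
    out
}
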