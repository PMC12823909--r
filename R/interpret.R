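#' Ensemble attention profile of one sample
#'
#' Raw attention is the arithmetic mean of each ensemble member's readout
#' attention simplex, renormalized to sum to 1; the CLR values divide by the
#' within-sample geometric mean and take the natural log (softmax outputs
#' are strictly positive, so no pseudocount is involved).
#'
#' @param models a [GATModel-class] or list of them (an ensemble).
#' @param graph a [SampleGraph-class].
#' @return an [AttentionProfile-class].
#' @export
attentionProfile <- function(models, graph) {
    if (is(models, "GATModel")) models <- list(models)
    A <- rowMeans(matrix(vapply(models,
                                function(m) gatForward(m, graph)$attention,
                                numeric(length(graph@genera))),
                         nrow = length(graph@genera)))
    A <- A / sum(A)
    names(A) <- graph@genera
    clr <- if (length(A) > 1L) clrTransform(A) else stats::setNames(0, names(A))
    new("AttentionProfile", sampleId = graph@sampleId, attention = A,
        clr = clr)
}

#' Identify test samples to aggregate attention over
#'
#' Returns the ids of samples whose true label is disease (1) and whose
#' ensemble prediction at the given threshold is also disease.
#'
#' @param models ensemble (list of [GATModel-class]).
#' @param graphs named list of [SampleGraph-class] objects.
#' @param labels named 0/1 vector.
#' @param threshold ensemble classification threshold.
#' @return character vector of sample ids.
#' @export
correctlyClassifiedDisease <- function(models, graphs, labels,
                                       threshold = 0.5) {
    ids <- names(graphs)
    probs <- ensemblePredict(models, graphs)
    ids[labels[ids] == 1L & probs >= threshold]
}

#' Rank genera by mean CLR-transformed attention
#'
#' For each genus, averages its CLR attention over the profiles in which it
#' is active; genera absent from every profile are excluded. Sorted in
#' descending order of the mean, ties broken lexicographically by genus id.
#'
#' @param profiles list of [AttentionProfile-class] objects (typically the
#'   correctly classified disease test samples).
#' @return data.frame with columns `rank`, `genus`, `mean_clr_attention`,
#'   `n_samples`.
#' @export
rankTaxa <- function(profiles) {
    if (!length(profiles)) stop("no qualifying sample: cannot rank taxa; ",
        "check that the ensemble classifies at least one disease test sample correctly")
    vals <- unlist(lapply(profiles, function(p) p@clr))
    genus <- unlist(lapply(profiles, function(p) names(p@clr)))
    mean_clr <- tapply(vals, genus, mean)
    nsup <- tapply(vals, genus, length)
    ord <- order(-mean_clr, names(mean_clr), method = "radix")
    data.frame(rank = seq_along(ord), genus = names(mean_clr)[ord],
               mean_clr_attention = unname(mean_clr[ord]),
               n_samples = as.integer(unname(nsup[ord])),
               stringsAsFactors = FALSE)
}

#' Stratify ranked genera into contribution groups
#'
#' Group A: genera with strictly positive mean CLR attention (taxa that
#' contribute to disease predictions); Group B: the remainder. A and B
#' partition the ranked genera.
#'
#' @param ranking output of [rankTaxa()].
#' @return list with character vectors `group_a`, `group_b`.
#' @export
stratifyGroups <- function(ranking) {
    if (!nrow(ranking)) stop("empty ranking")
    pos <- ranking$mean_clr_attention > 0
    list(group_a = ranking$genus[pos], group_b = ranking$genus[!pos])
}

#' Randomized in-silico taxon-removal intervention
#'
#' For each repetition and each sample, removes (sets to zero abundance)
#' `round(fraction * |group ∩ active genera|)` genera drawn uniformly
#' without replacement from the group, re-induces the sample graph and
#' re-predicts with the ensemble. The result is the mean over repetitions
#' and samples of (perturbed - baseline) probability; the p-value is the
#' two-sided Mann-Whitney U test between the baseline per-sample
#' probabilities and the pooled perturbed probabilities.
#'
#' Draws that would empty a sample's graph are redrawn (with a message);
#' samples for which the rounded removal count is zero contribute a zero
#' difference.
#'
#' @param models ensemble (list of [GATModel-class]).
#' @param experiment a [MicrobiomeExperiment-class].
#' @param samples sample ids to perturb (typically disease test samples).
#' @param network a [CoexpressionNetwork-class].
#' @param group character vector of genus ids to draw removals from.
#' @param removalFraction fraction in (0, 1).
#' @param nReps repetitions (default 100).
#' @param seed integer seed.
#' @param groupLabel label recorded in the result (e.g. "A" or "B").
#' @return one-row data.frame: `group`, `removal_fraction`, `mean_delta`,
#'   `p`, `n_repetitions`, `n_samples`, `seed`.
#' @export
runIntervention <- function(models, experiment, samples, network, group,
                            removalFraction, nReps = 100L, seed,
                            groupLabel = "A") {
    if (!length(group)) stop("group must be non-empty")
    if (removalFraction <= 0 || removalFraction >= 1)
        stop("removalFraction must lie in (0, 1)")
    if (missing(seed)) stop("seed is mandatory")
    ab <- abundances(experiment)
    emb <- genomicVectors(experiment)
    base_graphs <- lapply(samples, function(s)
        induceSampleGraph(network, ab[, s], embeddings = emb, sample = s))
    names(base_graphs) <- samples
    base_p <- ensemblePredict(models, base_graphs)

    deltas <- withr::with_seed(as.integer(seed), {
        pert <- matrix(NA_real_, length(samples), nReps,
                       dimnames = list(samples, NULL))
        for (r in seq_len(nReps)) {
            for (s in samples) {
                act <- base_graphs[[s]]@genera
                pool <- intersect(group, act)
                k <- floor(removalFraction * length(pool) + 0.5)
                # a draw can never be allowed to empty the graph entirely
                if (!length(setdiff(act, pool)) && k >= length(act))
                    k <- length(act) - 1L
                if (k == 0L) { pert[s, r] <- base_p[[s]]; next }
                repeat {
                    rem <- if (length(pool) == 1L) pool else sample(pool, k)
                    if (length(setdiff(act, rem))) break
                    message("redrawing removal that would empty sample ", s)
                }
                x <- ab[, s]; x[rem] <- 0
                gph <- induceSampleGraph(network, x, embeddings = emb,
                                         sample = s)
                pert[s, r] <- ensemblePredict(models, gph)
            }
        }
        pert
    })
    mean_delta <- mean(sweep(deltas, 1L, base_p, "-"))
    mw <- mannWhitneyU(base_p, as.numeric(deltas))
    data.frame(group = groupLabel, removal_fraction = removalFraction,
               mean_delta = mean_delta, p = mw$p,
               n_repetitions = as.integer(nReps),
               n_samples = length(samples), seed = as.integer(seed),
               stringsAsFactors = FALSE)
}

#' Write interpretation reports
#'
#' Writes the taxa ranking (rank, genus, mean CLR attention, support) and
#' the intervention grid (group x removal fraction with mean probability
#' difference and p-value) as TSVs, plus a JSON provenance record.
#' Re-running with identical inputs reproduces the files byte for byte.
#'
#' @param ranking output of [rankTaxa()].
#' @param interventions data.frame of [runIntervention()] rows (or NULL).
#' @param dir output directory (created if absent).
#' @param provenance named list stored in the JSON record (seeds, configs).
#' @return invisibly, the paths written.
#' @export
writeReports <- function(ranking, interventions = NULL, dir,
                         provenance = list()) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- file.path(dir, "taxa_ranking.tsv")
    utils::write.table(ranking, paths[[1L]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(interventions)) {
        p2 <- file.path(dir, "interventions.tsv")
        utils::write.table(interventions, p2, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        paths <- c(paths, p2)
    }
    p3 <- file.path(dir, "provenance.json")
    jsonlite::write_json(provenance, p3, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(c(paths, p3))
}
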