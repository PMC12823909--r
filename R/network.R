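#' Centered log-ratio transform
#'
#' `clr(x)_k = ln(x'_k / g(x'))` where `x'` replaces zero entries by
#' `pseudocount` (positive entries are untouched) and `g` is the geometric
#' mean of the adjusted vector. The output always sums to zero.
#'
#' @param x non-negative numeric vector, length >= 2.
#' @param pseudocount positive value substituted for zeros; ignored when the
#'   vector has none.
#' @return numeric zero-sum vector, same length/names as `x`.
#' @examples
#' clrTransform(c(1, 2, 4))   # (-log 2, 0, log 2)
#' @export
clrTransform <- function(x, pseudocount = NULL) {
    if (length(x) < 2L) stop("clrTransform needs a vector of length >= 2")
    if (any(x < 0) || anyNA(x)) stop("composition must be non-negative and finite")
    if (all(x == 0)) stop("cannot CLR-transform an all-zero vector")
    if (any(x == 0)) {
        if (is.null(pseudocount) || pseudocount <= 0)
            stop("a positive pseudocount is required when zeros are present")
        x[x == 0] <- pseudocount
    }
    lx <- log(x)
    lx - mean(lx)
}

.defaultPseudocount <- function(m) {
    nz <- m[m > 0]
    if (!length(nz)) stop("table has no positive entries")
    0.5 * min(nz)
}

#' COAT-style compositional correlation matrix
#'
#' Pearson correlation of CLR-transformed samples: each sample (row) is
#' CLR-transformed, then genus-genus correlations are computed column-pairwise.
#' This is the composition-adjusted correlation underlying the co-expression
#' network; the thresholding itself happens in [buildNetwork()].
#'
#' A genus whose CLR values are constant across samples has no defined
#' correlation; its off-diagonal entries are set to 0 (with a message) rather
#' than NaN.
#'
#' @param x a [MicrobiomeExperiment-class] or a samples x genera matrix.
#' @param pseudocount zero-replacement value; default half the smallest
#'   non-zero entry of the table.
#' @return symmetric genus x genus correlation matrix with unit diagonal.
#' @export
coatCorrelation <- function(x, pseudocount = NULL) {
    m <- if (is(x, "MicrobiomeExperiment")) t(abundances(x)) else as.matrix(x)
    if (nrow(m) < 3L) stop("coatCorrelation needs at least 3 samples")
    if (ncol(m) < 2L) stop("coatCorrelation needs at least 2 genera")
    if (is.null(pseudocount)) pseudocount <- .defaultPseudocount(m)
    z <- t(apply(m, 1L, clrTransform, pseudocount = pseudocount))
    # flat = numerically constant CLR column (no defined correlation)
    rng <- apply(z, 2L, function(v) diff(range(v)))
    flat <- rng <= 1e-12 * pmax(1, apply(abs(z), 2L, max))
    cc <- suppressWarnings(stats::cor(z))
    if (any(flat)) {
        message("zero-variance genus after CLR, correlations set to 0: ",
                paste(colnames(m)[flat], collapse = ", "))
        cc[flat, ] <- 0
        cc[, flat] <- 0
    }
    cc[!is.finite(cc)] <- 0
    diag(cc) <- 1
    dimnames(cc) <- list(colnames(m), colnames(m))
    cc
}

#' Build the global co-expression network with stability selection
#'
#' Draws `nSubsamples` subsets of `floor(subsampleFraction * n)` samples
#' without replacement (sequentially from a generator seeded with `seed`),
#' computes the COAT correlation matrix in each draw, and retains the edge
#' (i, j) iff `|c_ij| >= tau` in *every* draw with an identical sign. The
#' stored edge weight is the mean of the per-draw correlations.
#'
#' @param x a [MicrobiomeExperiment-class] or samples x genera matrix
#'   (normalized); may cover a larger sample pool than the training cohort.
#' @param tau correlation magnitude threshold (default 0.1).
#' @param nSubsamples number of draws (default 5).
#' @param subsampleFraction fraction per draw (default 0.8).
#' @param pseudocount zero replacement; default half the smallest non-zero
#'   value of the full table (shared across draws).
#' @param seed integer seed fixing the subsample index sets.
#' @return a [CoexpressionNetwork-class].
#' @export
buildNetwork <- function(x, tau = 0.1, nSubsamples = 5L,
                         subsampleFraction = 0.8, pseudocount = NULL,
                         seed) {
    if (missing(seed)) stop("seed is mandatory")
    m <- if (is(x, "MicrobiomeExperiment")) t(abundances(x)) else as.matrix(x)
    n <- nrow(m)
    nSubsamples <- as.integer(nSubsamples)
    if (nSubsamples < 1L) stop("nSubsamples must be >= 1")
    k <- floor(subsampleFraction * n)
    if (k < 3L) stop("subsample of ", k, " samples is too small (need >= 3)")
    if (is.null(pseudocount)) pseudocount <- .defaultPseudocount(m)

    draws <- withr::with_seed(as.integer(seed),
        lapply(seq_len(nSubsamples), function(s) sample.int(n, k)))
    cors <- lapply(draws, function(idx)
        coatCorrelation(m[idx, , drop = FALSE], pseudocount = pseudocount))

    p <- ncol(m)
    keep <- matrix(TRUE, p, p)
    sgn <- sign(cors[[1L]])
    acc <- matrix(0, p, p)
    for (cc in cors) {
        keep <- keep & (abs(cc) >= tau) & (sign(cc) == sgn)
        acc <- acc + cc
    }
    meanC <- acc / nSubsamples
    ut <- which(upper.tri(keep) & keep, arr.ind = TRUE)
    edges <- data.frame(
        from = colnames(m)[ut[, 1L]], to = colnames(m)[ut[, 2L]],
        weight = meanC[ut], stringsAsFactors = FALSE)
    edges <- edges[order(match(edges$from, colnames(m)),
                         match(edges$to, colnames(m))), , drop = FALSE]
    rownames(edges) <- NULL
    new("CoexpressionNetwork", genera = colnames(m), edges = edges,
        tau = tau, nSubsamples = nSubsamples,
        subsampleFraction = subsampleFraction, pseudocount = pseudocount,
        seed = as.integer(seed))
}

#' Induce the subgraph of one sample over its non-zero genera
#'
#' Nodes are the network genera with positive abundance in the sample; edges
#' are the network edges with both endpoints active. Each node carries its
#' percent abundance and genomic vector.
#'
#' @param network a [CoexpressionNetwork-class].
#' @param abundance named abundance vector for one sample (percent), or a
#'   [MicrobiomeExperiment-class] together with `sample`.
#' @param embeddings genus x d_g matrix covering the active genera (taken
#'   from the experiment when one is passed).
#' @param sample sample id (when `abundance` is an experiment).
#' @return a [SampleGraph-class]; an edgeless graph is allowed (and
#'   reported via a message), an empty node set is an error.
#' @export
induceSampleGraph <- function(network, abundance, embeddings = NULL,
                              sample = NULL) {
    if (is(abundance, "MicrobiomeExperiment")) {
        if (is.null(sample)) stop("give the sample id")
        if (is.null(embeddings)) embeddings <- genomicVectors(abundance)
        abundance <- abundances(abundance)[, sample]
    }
    sid <- if (!is.null(sample)) sample else "sample"
    act <- network@genera[network@genera %in% names(abundance)[abundance > 0]]
    if (!length(act))
        stop("sample '", sid, "' has no active genus in the network; ",
             "it cannot be embedded")
    if (is.null(embeddings)) stop("genomic vectors are required")
    missing <- setdiff(act, rownames(embeddings))
    if (length(missing))
        stop("no genomic vector for genus: ", paste(missing, collapse = ", "))
    e <- network@edges
    idx <- match(e$from, act)
    jdx <- match(e$to, act)
    ok <- !is.na(idx) & !is.na(jdx)
    em <- cbind(pmin(idx[ok], jdx[ok]), pmax(idx[ok], jdx[ok]))
    storage.mode(em) <- "integer"
    if (!nrow(em) && length(act) > 1L)
        message("sample '", sid, "': induced graph has no edges")
    new("SampleGraph", sampleId = sid, genera = act,
        abundance = unname(abundance[act]),
        genomic = embeddings[act, , drop = FALSE], edges = em)
}

#' Induce sample graphs for every sample of an experiment
#'
#' @param network a [CoexpressionNetwork-class].
#' @param x a [MicrobiomeExperiment-class].
#' @param samples sample ids (default: all).
#' @return named list of [SampleGraph-class] objects.
#' @export
sampleGraphs <- function(network, x, samples = colnames(x)) {
    gl <- lapply(samples, function(s)
        induceSampleGraph(network, x, sample = s))
    stats::setNames(gl, samples)
}

#' Randomly rewire a sample graph, preserving node set and edge count
#'
#' Replaces the edge set by a uniform draw of the same number of unordered
#' node pairs (no self-loops, no duplicates). Used by the shuffled-edge
#' ablation.
#'
#' @param graph a [SampleGraph-class] with >= 2 nodes.
#' @param seed integer seed; same seed, same rewiring.
#' @return a [SampleGraph-class].
#' @export
shuffleEdges <- function(graph, seed) {
    n <- length(graph@genera)
    if (n < 2L) stop("shuffleEdges needs at least 2 nodes")
    m <- nrow(graph@edges)
    npairs <- n * (n - 1L) / 2
    if (m > npairs) stop("edge count exceeds the number of possible pairs")
    if (m == 0L) return(graph)
    pick <- withr::with_seed(as.integer(seed), sample.int(npairs, m))
    # unrank: pair t -> (i, j), enumerated as (1,2), (1,3), ..., (n-1, n)
    pick <- sort(pick)
    i <- findInterval(pick - 1L, cumsum(c(0L, (n - 1L):1L)),
                      rightmost.closed = FALSE)
    offset <- pick - (cumsum(c(0L, (n - 1L):1L)))[i]
    em <- cbind(i, i + offset, deparse.level = 0)
    dimnames(em) <- NULL
    storage.mode(em) <- "integer"
    graph@edges <- em
    validObject(graph)
    graph
}
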