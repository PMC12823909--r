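#' Binary classification metrics
#'
#' AUROC is the rank statistic over all positive-negative pairs (ties count
#' one half); AUPRC integrates the precision-recall curve stepwise over
#' distinct score thresholds; F1 is computed at the stated probability
#' threshold.
#'
#' @param probabilities predicted probabilities.
#' @param labels 0/1 vector, same length.
#' @param threshold classification threshold for F1 (default 0.5).
#' @return list with `auroc`, `auprc`, `f1`.
#' @examples
#' computeMetrics(c(0.9, 0.8, 0.3), c(1, 0, 1))$auroc  # 0.5
#' @export
computeMetrics <- function(probabilities, labels, threshold = 0.5) {
    stopifnot(length(probabilities) == length(labels))
    labels <- as.integer(labels)
    n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
    if (n1 == 0L || n0 == 0L)
        stop("both classes must be present to compute metrics")
    r <- rank(probabilities)               # midranks handle ties as 1/2
    auroc <- (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)

    ord <- order(probabilities, decreasing = TRUE)
    y <- labels[ord]; p <- probabilities[ord]
    tp <- cumsum(y); fp <- cumsum(1L - y)
    last <- c(p[-1L] != p[-length(p)], TRUE)  # evaluate at distinct thresholds
    tp <- tp[last]; fp <- fp[last]
    prec <- tp / (tp + fp); rec <- tp / n1
    auprc <- sum(diff(c(0, rec)) * prec)

    pred <- as.integer(probabilities >= threshold)
    tp2 <- sum(pred == 1L & labels == 1L)
    f1 <- if (tp2 == 0L) 0 else {
        precision <- tp2 / sum(pred == 1L)
        recall <- tp2 / n1
        2 * precision * recall / (precision + recall)
    }
    list(auroc = auroc, auprc = auprc, f1 = f1)
}

#' Per-seed and ensemble metrics report
#'
#' Mirrors the mean (sd), 95% CI, plus-ensemble presentation used for model
#' comparisons: per-seed metrics, their mean, standard deviation and normal
#' 95% confidence interval (mean +/- 1.96 sd/sqrt(runs)), and the metrics of
#' the probability-averaged ensemble.
#'
#' @param perSeedProbs matrix (samples x seeds) or list of probability
#'   vectors.
#' @param labels 0/1 vector.
#' @param threshold F1 threshold.
#' @return list with `per_seed` (data.frame), `summary` (data.frame with
#'   mean/sd/ci per metric) and `ensemble` (list).
#' @export
metricsReport <- function(perSeedProbs, labels, threshold = 0.5) {
    if (is.list(perSeedProbs)) perSeedProbs <- do.call(cbind, perSeedProbs)
    per <- apply(perSeedProbs, 2L, computeMetrics, labels = labels,
                 threshold = threshold)
    perdf <- do.call(rbind, lapply(per, as.data.frame))
    perdf$seed_run <- seq_len(nrow(perdf))
    k <- nrow(perdf)
    summ <- do.call(rbind, lapply(c("auroc", "auprc", "f1"), function(mt) {
        v <- perdf[[mt]]
        data.frame(metric = mt, mean = mean(v), sd = stats::sd(v),
                   ci_lo = mean(v) - 1.96 * stats::sd(v) / sqrt(k),
                   ci_hi = mean(v) + 1.96 * stats::sd(v) / sqrt(k))
    }))
    ens <- computeMetrics(rowMeans(perSeedProbs), labels, threshold)
    list(per_seed = perdf, summary = summ, ensemble = ens)
}

#' Mann-Whitney U test
#'
#' For combined sample sizes up to 12 the two-sided p-value is computed by
#' exhaustive enumeration of all group assignments of the pooled values
#' (exact even under ties); larger samples use the normal approximation with
#' tie-corrected variance.
#'
#' @param groupA,groupB numeric vectors.
#' @param alternative only "two.sided" is provided.
#' @return list with `U` (statistic of `groupA`) and `p`.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mannWhitneyU <- function(groupA, groupB, alternative = "two.sided") {
    alternative <- match.arg(alternative, "two.sided")
    if (!length(groupA) || !length(groupB)) stop("both groups must be non-empty")
    nA <- length(groupA); nB <- length(groupB)
    pooled <- c(groupA, groupB)
    r <- rank(pooled)
    U <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
    n <- nA + nB
    if (n <= 12L) {
        combs <- utils::combn(n, nA)
        ustats <- apply(combs, 2L, function(idx)
            sum(r[idx]) - nA * (nA + 1) / 2)
        mu <- nA * nB / 2
        p <- mean(abs(ustats - mu) >= abs(U - mu) - 1e-12)
    } else {
        ties <- table(pooled)
        mu <- nA * nB / 2
        sig2 <- nA * nB / 12 *
            (n + 1 - sum(ties^3 - ties) / (n * (n - 1)))
        if (sig2 <= 0) return(list(U = U, p = 1))
        z <- (U - mu) / sqrt(sig2)
        p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    list(U = U, p = p)
}

#' Silhouette separation of graph embeddings, with a permutation p-value
#'
#' Mean silhouette width (Euclidean distance) of the class labels over the
#' per-sample embedding vectors, and a p-value from a seeded
#' label-permutation null: the proportion of permuted scores at least as
#' large as the observed one, with the +1 correction.
#'
#' @param embeddings samples x d matrix (e.g. pooled graph embeddings).
#' @param labels 0/1 vector, length `nrow(embeddings)`; each class needs at
#'   least two members.
#' @param nPermutations size of the permutation null (default 999).
#' @param seed integer seed for the permutations.
#' @return list with `score` and `p`.
#' @export
graphEmbeddingSilhouette <- function(embeddings, labels, nPermutations = 999L,
                                     seed = 1L) {
    embeddings <- as.matrix(embeddings)
    labels <- as.integer(labels)
    if (min(table(labels)) < 2L) stop("each class needs at least 2 samples")
    d <- stats::dist(embeddings)
    score_of <- function(lab) mean(cluster::silhouette(lab + 1L, d)[, 3L])
    obs <- score_of(labels)
    perm <- withr::with_seed(as.integer(seed),
        vapply(seq_len(nPermutations),
               function(i) score_of(sample(labels)), numeric(1L)))
    list(score = obs, p = (1 + sum(perm >= obs)) / (nPermutations + 1))
}
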