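#' Configuration for the zero-inflated logistic-normal simulator
#'
#' Validated parameter container for [generateDataset()]. The generative
#' model (per sample s, genus g): latent log-abundance
#' `x = mu_g + y_s * sign_g * effect_size + sqrt(rho) * z_{s,b(g)} +
#' sqrt(1 - rho) * eps`, where `mu_g ~ N(0, 1)` is a genus base level,
#' `z_{s,b}` a per-sample per-block factor inducing within-block correlation
#' exactly `rho` on the log scale, `eps ~ N(0, 1)` residual noise and
#' `sign_g` alternates +/- over the discriminative genera. Abundances
#' `exp(x)` are independently zeroed with probability `zero_inflation` and
#' each sample is then closed to a sum of 100.
#'
#' @param n_samples,n_genera table dimensions.
#' @param n_blocks,block_size planted co-abundance blocks (first
#'   `n_blocks * block_size` genera).
#' @param block_rho within-block log-scale correlation, in \[0, 1).
#' @param n_discriminative genera whose mean log-abundance shifts with class.
#' @param effect_size log-scale mean shift magnitude.
#' @param zero_inflation probability any abundance cell is zeroed.
#' @param class_balance proportion of disease (label 1) samples.
#' @param embedding_dim dimension of the per-genus genomic vectors.
#' @param discriminativeInBlocks if TRUE the discriminative genera are block
#'   members (class signal coupled to network structure); if FALSE (default)
#'   they are taken from outside the blocks.
#' @param embeddingSignal if TRUE, discriminative genera receive a shared
#'   offset in embedding space (genomic vectors become informative of
#'   discriminative identity); default FALSE: embeddings carry no signal.
#' @param seed integer seed; mandatory.
#' @return a validated list of class `simulation_config`.
#' @export
simulationConfig <- function(n_samples = 200L, n_genera = 60L, n_blocks = 4L,
                             block_size = 8L, block_rho = 0.7,
                             n_discriminative = 10L, effect_size = 1.5,
                             zero_inflation = 0.2, class_balance = 0.5,
                             embedding_dim = 32L,
                             discriminativeInBlocks = FALSE,
                             embeddingSignal = FALSE, seed) {
    if (missing(seed)) stop("seed is mandatory")
    cfg <- list(n_samples = as.integer(n_samples),
                n_genera = as.integer(n_genera),
                n_blocks = as.integer(n_blocks),
                block_size = as.integer(block_size), block_rho = block_rho,
                n_discriminative = as.integer(n_discriminative),
                effect_size = effect_size, zero_inflation = zero_inflation,
                class_balance = class_balance,
                embedding_dim = as.integer(embedding_dim),
                discriminativeInBlocks = isTRUE(discriminativeInBlocks),
                embeddingSignal = isTRUE(embeddingSignal),
                seed = as.integer(seed))
    counts <- cfg[c("n_samples", "n_genera", "embedding_dim")]
    if (any(vapply(counts, function(v) v < 1L, TRUE)))
        stop("n_samples, n_genera and embedding_dim must be positive")
    if (cfg$n_blocks < 0L || cfg$block_size < 0L || cfg$n_discriminative < 0L)
        stop("counts must be non-negative")
    if (cfg$zero_inflation < 0 || cfg$zero_inflation > 1 ||
        cfg$class_balance < 0 || cfg$class_balance > 1 ||
        cfg$block_rho < 0 || cfg$block_rho >= 1)
        stop("probabilities must lie in [0, 1] (block_rho in [0, 1))")
    if (cfg$n_blocks * cfg$block_size > cfg$n_genera)
        stop("n_blocks * block_size exceeds n_genera")
    if (!cfg$discriminativeInBlocks &&
        cfg$n_discriminative > cfg$n_genera - cfg$n_blocks * cfg$block_size)
        stop("not enough non-block genera for the discriminative set; ",
             "use discriminativeInBlocks = TRUE or fewer blocks")
    if (cfg$discriminativeInBlocks &&
        cfg$n_discriminative > cfg$n_blocks * cfg$block_size)
        stop("not enough block genera for the discriminative set")
    class(cfg) <- "simulation_config"
    cfg
}

#' Generate a two-class zero-inflated compositional dataset
#'
#' Draws a dataset under the logistic-normal scheme described in
#' [simulationConfig()], with planted co-abundance blocks, planted
#' class-discriminative genera, independent zero-inflation applied before
#' closure, and seed-fixed unit-norm random genomic vectors. Identical
#' config (including seed) gives bit-identical output.
#'
#' @param config a [simulationConfig()].
#' @return list with `experiment` (a [MicrobiomeExperiment-class]) and
#'   `truth` (list: `discriminative` genus ids, `blocks` named integer
#'   vector of block memberships, NA for unblocked genera).
#' @examples
#' sim <- generateDataset(simulationConfig(n_samples = 40, seed = 1))
#' sim$truth$discriminative
#' @export
generateDataset <- function(config) {
    stopifnot(inherits(config, "simulation_config"))
    c_ <- config
    withr::with_seed(c_$seed, {
        gid <- sprintf("g%03d", seq_len(c_$n_genera))
        sid <- sprintf("s%03d", seq_len(c_$n_samples))
        n1 <- round(c_$class_balance * c_$n_samples)
        y <- c(rep(1L, n1), rep(0L, c_$n_samples - n1))

        blocks <- rep(NA_integer_, c_$n_genera)
        nb <- c_$n_blocks * c_$block_size
        if (nb > 0L) blocks[seq_len(nb)] <- rep(seq_len(c_$n_blocks),
                                                each = c_$block_size)
        names(blocks) <- gid
        disc_idx <- if (c_$n_discriminative == 0L) integer() else if
            (c_$discriminativeInBlocks) seq_len(c_$n_discriminative) else
            seq(c_$n_genera - c_$n_discriminative + 1L, c_$n_genera)
        sign_g <- numeric(c_$n_genera)
        if (length(disc_idx))
            sign_g[disc_idx] <- rep_len(c(1, -1), length(disc_idx))

        mu <- stats::rnorm(c_$n_genera)
        z <- matrix(stats::rnorm(c_$n_samples * max(c_$n_blocks, 1L)),
                    c_$n_samples)
        eps <- matrix(stats::rnorm(c_$n_samples * c_$n_genera), c_$n_samples)
        xlog <- sweep(eps, 2L, sqrt(1 - ifelse(is.na(blocks), 0, c_$block_rho)), "*")
        for (g in seq_len(c_$n_genera)) {
            if (!is.na(blocks[g]))
                xlog[, g] <- xlog[, g] + sqrt(c_$block_rho) * z[, blocks[g]]
            xlog[, g] <- xlog[, g] + mu[g] + y * sign_g[g] * c_$effect_size
        }
        w <- exp(xlog)
        if (c_$zero_inflation > 0) {
            mask <- matrix(stats::runif(length(w)) < c_$zero_inflation,
                           nrow(w))
            w[mask] <- 0
            dead <- rowSums(w) == 0
            if (any(dead))  # keep each sample's dominant genus alive
                for (s in which(dead)) {
                    g <- which.max(exp(xlog[s, ]))
                    w[s, g] <- exp(xlog[s, g])
                }
        }
        dimnames(w) <- list(sid, gid)
        w <- normalizeToPercent(w)

        emb <- matrix(stats::rnorm(c_$n_genera * c_$embedding_dim),
                      c_$n_genera, dimnames = list(gid, NULL))
        if (c_$embeddingSignal && length(disc_idx)) {
            offset <- stats::rnorm(c_$embedding_dim)
            emb[disc_idx, ] <- emb[disc_idx, ] +
                matrix(offset, length(disc_idx), c_$embedding_dim, byrow = TRUE)
        }
        emb <- emb / sqrt(rowSums(emb^2))
        colnames(emb) <- paste0("d", seq_len(c_$embedding_dim))

        list(experiment = MicrobiomeExperiment(
                 w, labels = stats::setNames(y, sid), embeddings = emb),
             truth = list(discriminative = gid[disc_idx], blocks = blocks))
    })
}

#' Hard-coded 8-sample x 6-genus toy dataset
#'
#' A fixed miniature dataset (4 disease / 4 control samples, 4-dimensional
#' genomic vectors, rows closed to 100) used in documentation and unit
#' tests. Values are committed constants; repeated calls return identical
#' objects.
#'
#' @return a [MicrobiomeExperiment-class].
#' @export
makeToyFixture <- function() {
    gid <- paste0("g", 1:6)
    sid <- paste0("s", 1:8)
    a <- matrix(c(
        30, 20, 10, 25, 10,  5,
         0, 40, 20, 20, 10, 10,
        25, 25, 25, 25,  0,  0,
        10, 10, 40, 20, 10, 10,
        50, 10,  5, 15, 10, 10,
         5, 45, 10, 10, 20, 10,
        20,  0, 30, 30, 10, 10,
        15, 15, 15, 15, 20, 20), nrow = 8, byrow = TRUE,
        dimnames = list(sid, gid))
    labels <- stats::setNames(c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L), sid)
    emb <- matrix(c(
         0.9, -0.1,  0.2,  0.4,
        -0.3,  0.8,  0.1, -0.5,
         0.2,  0.3, -0.9,  0.1,
        -0.6, -0.4,  0.3,  0.7,
         0.5,  0.5,  0.5, -0.5,
         0.1, -0.7, -0.2, -0.6), nrow = 6, byrow = TRUE,
        dimnames = list(gid, paste0("d", 1:4)))
    MicrobiomeExperiment(a, labels = labels, embeddings = emb)
}
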