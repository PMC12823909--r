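# Shared miniature objects; everything is generated in code.

toy_experiment <- function() makeToyFixture()

toy_network <- function(seed = 3L) {
    # 2 subsamples at 100% keeps the toy network deterministic and dense
    buildNetwork(makeToyFixture(), tau = 0.1, nSubsamples = 2L,
                 subsampleFraction = 1.0, seed = seed)
}

small_model_config <- function(...) {
    args <- list(n_layers = 3L, n_heads = 2L, per_head_dim = 4L,
                 abundance_dim = 8L, genomic_dim = 4L,
                 mlp_hidden = c(8L, 4L))
    do.call(modelConfig, utils::modifyList(args, list(...)))
}

# study-scale configuration used for the synthetic evaluation runs
study_model_config <- function(...) {
    args <- list(n_heads = 8L, per_head_dim = 8L, abundance_dim = 16L,
                 genomic_dim = 32L, mlp_hidden = c(16L, 8L))
    do.call(modelConfig, utils::modifyList(args, list(...)))
}

# brute-force CLR + textbook Pearson, written independently of the package
# implementation (explicit loops)
bruteforce_coat <- function(m, pseudocount) {
    z <- matrix(NA_real_, nrow(m), ncol(m))
    for (i in seq_len(nrow(m))) {
        x <- m[i, ]
        x[x == 0] <- pseudocount
        lx <- log(x)
        z[i, ] <- lx - mean(lx)
    }
    p <- ncol(m)
    cc <- diag(1, p)
    for (a in seq_len(p - 1)) for (b in (a + 1):p) {
        xa <- z[, a]; xb <- z[, b]
        num <- sum((xa - mean(xa)) * (xb - mean(xb)))
        den <- sqrt(sum((xa - mean(xa))^2) * sum((xb - mean(xb))^2))
        cc[a, b] <- cc[b, a] <- if (den == 0) 0 else num / den
    }
    dimnames(cc) <- list(colnames(m), colnames(m))
    cc
}
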