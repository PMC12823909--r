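test_that("clrTransform matches hand computations and sums to zero", {
    expect_equal(clrTransform(c(5, 5, 5)), c(0, 0, 0))
    expect_equal(clrTransform(c(1, 2, 4)), c(-log(2), 0, log(2)))
    withr::with_seed(7, for (i in 1:20) {
        x <- rexp(sample(3:12, 1))
        expect_equal(sum(clrTransform(x)), 0, tolerance = 1e-9)
    })
    expect_error(clrTransform(c(0, 0, 0)), "all-zero")
    expect_error(clrTransform(c(1, 0, 2)), "pseudocount")
    # pseudocount only touches zeros
    expect_equal(clrTransform(c(1, 0, 1), pseudocount = 1), c(0, 0, 0))
})

test_that("coatCorrelation equals the brute-force CLR+Pearson oracle", {
    for (seed in 1:20) {
        sim <- generateDataset(simulationConfig(
            n_samples = 10, n_genera = 5, n_blocks = 1, block_size = 3,
            n_discriminative = 2, zero_inflation = 0, seed = seed))
        m <- t(abundances(sim$experiment))
        pc <- 0.5 * min(m[m > 0])
        expect_lt(max(abs(coatCorrelation(m) - bruteforce_coat(m, pc))),
                  1e-10)
    }
})

test_that("degenerate coat inputs follow the zero-variance rule", {
    m <- cbind(g1 = c(1, 2, 3, 4), g2 = c(1, 2, 3, 4) * 3,
               g3 = c(4, 3, 1, 2))
    rownames(m) <- paste0("s", 1:4)
    cc <- coatCorrelation(m)
    expect_equal(cc["g1", "g2"], 1.0)   # proportional columns, identical CLR
    m2 <- cbind(m, g4 = rep(2, 4))      # g4 constant share after closure?
    m2 <- m2 / rowSums(m2) * 100
    # force an exactly constant CLR column: two samples repeated
    m3 <- rbind(a = c(1, 2, 4), b = c(2, 4, 8), c = c(4, 8, 16))
    colnames(m3) <- paste0("g", 1:3)
    expect_message(cc3 <- coatCorrelation(m3), "zero-variance")
    # every column has zero CLR variance here
    expect_true(all(cc3[upper.tri(cc3)] == 0))
    expect_true(all(diag(cc3) == 1))
})

test_that("buildNetwork applies the stability retention rule exactly", {
    sim <- generateDataset(simulationConfig(
        n_samples = 40, n_genera = 12, n_blocks = 1, block_size = 5,
        n_discriminative = 0, zero_inflation = 0.1, seed = 13))
    m <- t(abundances(sim$experiment))
    tau <- 0.1; S <- 5L; frac <- 0.8; seed <- 99L
    net <- buildNetwork(m, tau = tau, nSubsamples = S,
                        subsampleFraction = frac, seed = seed)
    # independent re-implementation: same seeded index draws, loop retention
    pc <- 0.5 * min(m[m > 0])
    idx_sets <- withr::with_seed(seed,
        lapply(1:S, function(s) sample.int(nrow(m), floor(frac * nrow(m)))))
    mats <- lapply(idx_sets, function(ii) bruteforce_coat(m[ii, ], pc))
    expected <- list()
    p <- ncol(m)
    for (a in seq_len(p - 1)) for (b in (a + 1):p) {
        vals <- vapply(mats, function(cc) cc[a, b], numeric(1))
        if (all(abs(vals) >= tau) && all(vals != 0) &&
            length(unique(sign(vals))) == 1L)
            expected[[length(expected) + 1L]] <- data.frame(
                from = colnames(m)[a], to = colnames(m)[b],
                weight = mean(vals))
    }
    expected <- do.call(rbind, expected)
    got <- networkEdges(net)
    expect_identical(paste(got$from, got$to),
                     paste(expected$from, expected$to))
    expect_equal(got$weight, expected$weight, tolerance = 1e-12)
    # determinism
    net2 <- buildNetwork(m, tau = tau, nSubsamples = S,
                         subsampleFraction = frac, seed = seed)
    expect_identical(networkEdges(net), networkEdges(net2))
})

test_that("threshold behaves monotonically and degenerately as expected", {
    toy <- makeToyFixture()
    m <- t(abundances(toy))
    # tau = 0, one subsample over all samples: all non-zero-correlation pairs
    net0 <- buildNetwork(m, tau = 0, nSubsamples = 1, subsampleFraction = 1,
                         seed = 1)
    cc <- coatCorrelation(m)
    expect_identical(nrow(networkEdges(net0)),
                     sum(cc[upper.tri(cc)] != 0))
    netHi <- buildNetwork(m, tau = 1.01, nSubsamples = 1,
                          subsampleFraction = 1, seed = 1)
    expect_identical(nrow(networkEdges(netHi)), 0L)
    # edge set at tau = 0.2 is a subset of tau = 0.1 under the same seed
    sim <- generateDataset(simulationConfig(n_samples = 60, n_genera = 15,
                                            n_blocks = 2, block_size = 4,
                                            n_discriminative = 5, seed = 8))
    e1 <- networkEdges(buildNetwork(sim$experiment, tau = 0.1, seed = 5))
    e2 <- networkEdges(buildNetwork(sim$experiment, tau = 0.2, seed = 5))
    expect_true(all(paste(e2$from, e2$to) %in% paste(e1$from, e1$to)))
})

test_that("a planted co-abundance block is recovered by the network", {
    # one strong block (log-scale correlation 0.8, observed CLR correlation
    # ~0.7) in a dense table; closure-induced spurious correlations shrink
    # with the number of genera, so this uses a 150-genus table
    sim <- generateDataset(simulationConfig(
        n_samples = 300, n_genera = 150, n_blocks = 1, block_size = 8,
        n_discriminative = 0, block_rho = 0.8, zero_inflation = 0,
        seed = 17))
    net <- buildNetwork(sim$experiment, seed = 17)
    blocks <- sim$truth$blocks
    inblock <- names(blocks)[!is.na(blocks)]
    e <- networkEdges(net)
    key <- paste(e$from, e$to)
    all_pairs <- t(combn(names(blocks), 2))
    is_within <- all_pairs[, 1] %in% inblock & all_pairs[, 2] %in% inblock
    within_hit <- mean(paste(all_pairs[is_within, 1],
                             all_pairs[is_within, 2]) %in% key)
    cross_hit <- mean(paste(all_pairs[!is_within, 1],
                            all_pairs[!is_within, 2]) %in% key)
    expect_gte(within_hit, 0.8)
    expect_lte(cross_hit, 0.05)
})

test_that("sample graphs contain exactly the active genera and induced edges", {
    toy <- makeToyFixture()
    net <- toy_network()
    g3 <- induceSampleGraph(net, toy, sample = "s3")  # g5, g6 are zero
    expect_identical(activeGenera(g3), paste0("g", 1:4))
    e <- networkEdges(net)
    expected <- e[e$from %in% paste0("g", 1:4) & e$to %in% paste0("g", 1:4), ]
    got <- cbind(activeGenera(g3)[g3@edges[, 1]],
                 activeGenera(g3)[g3@edges[, 2]])
    expect_identical(unname(got), unname(as.matrix(expected[, 1:2])))
    # all genera active: graph equals the global network
    g8 <- induceSampleGraph(net, toy, sample = "s8")
    expect_identical(length(activeGenera(g8)), length(networkGenera(net)))
    expect_identical(nrow(g8@edges), nrow(e))
    # single non-zero genus: 1 node, 0 edges
    ab <- c(g1 = 5, g2 = 0, g3 = 0, g4 = 0, g5 = 0, g6 = 0)
    g1 <- induceSampleGraph(net, ab, embeddings = genomicVectors(toy),
                            sample = "lonely")
    expect_identical(length(activeGenera(g1)), 1L)
    expect_identical(nrow(g1@edges), 0L)
    # no active genus: hard error
    expect_error(induceSampleGraph(net, ab * 0,
                                   embeddings = genomicVectors(toy),
                                   sample = "void"), "no active genus")
    # invariant: every edge endpoint active, across all fixture samples
    for (s in colnames(toy)) {
        g <- induceSampleGraph(net, toy, sample = s)
        if (nrow(g@edges))
            expect_true(all(g@edges >= 1 & g@edges <= length(activeGenera(g))))
    }
})

test_that("edge shuffling preserves node set and edge count, reproducibly", {
    toy <- makeToyFixture()
    net <- toy_network()
    g <- induceSampleGraph(net, toy, sample = "s8")
    s1 <- shuffleEdges(g, seed = 11)
    s2 <- shuffleEdges(g, seed = 11)
    expect_identical(s1@edges, s2@edges)
    expect_identical(nrow(s1@edges), nrow(g@edges))
    expect_identical(activeGenera(s1), activeGenera(g))
    expect_true(all(s1@edges[, 1] < s1@edges[, 2]))  # no self-loops
    expect_false(anyDuplicated(paste(s1@edges[, 1], s1@edges[, 2])) > 0)
    s3 <- shuffleEdges(g, seed = 12)
    expect_false(identical(s1@edges, s3@edges))
    # 2-node graph with its only possible edge is unchanged
    ab <- c(g1 = 5, g2 = 0, g3 = 4, g4 = 0, g5 = 0, g6 = 0)
    g2 <- induceSampleGraph(net, ab, embeddings = genomicVectors(toy),
                            sample = "pair")
    if (nrow(g2@edges) == 1L)
        expect_identical(shuffleEdges(g2, seed = 1)@edges, g2@edges)
})
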