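test_that("initialization and evaluation are deterministic", {
    toy <- makeToyFixture()
    net <- toy_network()
    g <- induceSampleGraph(net, toy, sample = "s1")
    m1 <- initModel(small_model_config(), seed = 7)
    m2 <- initModel(small_model_config(), seed = 7)
    expect_identical(m1@params, m2@params)
    expect_identical(gatForward(m1, g)$prob, gatForward(m1, g)$prob)
    expect_false(identical(m1@params,
                           initModel(small_model_config(), seed = 8)@params))
})

test_that("every softmax normalizes and the output is a probability", {
    toy <- makeToyFixture()
    net <- toy_network()
    m <- initModel(small_model_config(), seed = 1)
    for (s in colnames(toy)) {
        fw <- gatForward(m, induceSampleGraph(net, toy, sample = s))
        expect_equal(sum(fw$attention), 1, tolerance = 1e-6)
        expect_true(all(fw$attention > 0))
        expect_gt(fw$prob, 0)
        expect_lt(fw$prob, 1)
    }
})

test_that("prediction is invariant to node relabeling and edge order", {
    withr::with_seed(31, {
        for (rep in 1:10) {
            sim <- generateDataset(simulationConfig(
                n_samples = 20, n_genera = 12, n_blocks = 1, block_size = 4,
                n_discriminative = 3, zero_inflation = 0.2,
                embedding_dim = 4, seed = 400 + rep))
            net <- buildNetwork(sim$experiment, tau = 0.05, nSubsamples = 2,
                                seed = rep)
            s <- sample(colnames(sim$experiment), 1)
            g <- induceSampleGraph(net, sim$experiment, sample = s)
            m <- initModel(modelConfig(n_layers = 2, n_heads = 2,
                                       per_head_dim = 4, abundance_dim = 4,
                                       genomic_dim = 4,
                                       mlp_hidden = c(4, 3)), seed = rep)
            p0 <- gatForward(m, g)$prob
            # permute node order, remap edges accordingly
            n <- length(g@genera)
            perm <- sample(n)
            gp <- g
            gp@genera <- g@genera[perm]
            gp@abundance <- g@abundance[perm]
            gp@genomic <- g@genomic[perm, , drop = FALSE]
            inv <- order(perm)
            if (nrow(g@edges)) {
                e <- cbind(inv[g@edges[, 1]], inv[g@edges[, 2]])
                e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
                e <- e[sample(nrow(e)), , drop = FALSE]  # reorder edge list
                dimnames(e) <- NULL
                storage.mode(e) <- "integer"
                gp@edges <- e
            }
            expect_lt(abs(gatForward(m, gp)$prob - p0), 1e-5)
        }
    })
})

test_that("indistinguishable nodes share the attention mass uniformly", {
    # 5-node clique, equal abundance, zero genomic vectors
    n <- 5L
    genera <- paste0("g", 1:n)
    edges <- t(combn(n, 2L))
    dimnames(edges) <- NULL
    storage.mode(edges) <- "integer"
    g <- new("SampleGraph", sampleId = "clique", genera = genera,
             abundance = rep(20, n), genomic = matrix(0, n, 4),
             edges = edges)
    m <- initModel(small_model_config(), seed = 3)
    fw <- gatForward(m, g)
    expect_equal(fw$attention, setNames(rep(0.2, n), genera),
                 tolerance = 1e-9)
})

test_that("single-node graphs degenerate correctly", {
    toy <- makeToyFixture()
    net <- toy_network()
    ab <- c(g1 = 7, g2 = 0, g3 = 0, g4 = 0, g5 = 0, g6 = 0)
    g <- induceSampleGraph(net, ab, embeddings = genomicVectors(toy),
                           sample = "solo")
    m <- initModel(small_model_config(), seed = 5)
    fw <- gatForward(m, g)
    expect_equal(unname(fw$attention), 1.0)
    expect_equal(fw$pooled, fw$node_embed[1, ], ignore_attr = TRUE)
})

test_that("analytic gradients match numerical differentiation", {
    toy <- makeToyFixture()
    net <- toy_network()
    graphs <- list(induceSampleGraph(net, toy, sample = "s3"),
                   induceSampleGraph(net, toy, sample = "s5"))
    m <- initModel(small_model_config(), seed = 2)
    pay <- lapply(graphs, microGAT:::.graphPayload, genomicDim = 4L)
    y <- c(1, 0)
    an <- unlist(microGAT:::.gatBatchCpp(m@params, m@config, pay, y,
                                         FALSE, TRUE)$grads,
                 use.names = FALSE)
    v0 <- unlist(m@params, use.names = FALSE)
    loss_at <- function(v) {
        p <- utils::relist(v, m@params)
        microGAT:::.gatBatchCpp(p, m@config, pay, y, FALSE, FALSE)$loss
    }
    idx <- withr::with_seed(4, sample(length(v0), 60))
    eps <- 1e-6
    for (i in idx) {
        vp <- v0; vp[i] <- vp[i] + eps
        vm <- v0; vm[i] <- vm[i] - eps
        num <- (loss_at(vp) - loss_at(vm)) / (2 * eps)
        expect_lt(abs(num - an[i]),
                  1e-4 * max(1e-3, abs(num) + abs(an[i])))
    }
})

test_that("ensembles average member probabilities", {
    toy <- makeToyFixture()
    net <- toy_network()
    g <- induceSampleGraph(net, toy, sample = "s2")
    m1 <- initModel(small_model_config(), seed = 1)
    m2 <- initModel(small_model_config(), seed = 2)
    p1 <- predictProb(m1, g); p2 <- predictProb(m2, g)
    expect_equal(ensemblePredict(list(m1, m2), g), (p1 + p2) / 2)
    expect_equal(ensemblePredict(list(m1), g), p1)
    expect_equal(ensemblePredict(list(m1, m1), g), p1)
    m3 <- initModel(small_model_config(n_heads = 3L), seed = 1)
    expect_error(ensemblePredict(list(m1, m3), g), "identical configuration")
})

test_that("models serialize and restore bit-identically", {
    m <- initModel(small_model_config(), seed = 9)
    d <- withr::local_tempdir()
    f <- file.path(d, "model.rds")
    saveModel(m, f, configPath = file.path(d, "cfg.json"))
    back <- readModel(f)
    expect_identical(back@params, m@params)
    expect_identical(back@config, m@config)
    cfg <- jsonlite::read_json(file.path(d, "cfg.json"))
    expect_identical(cfg$n_heads, 2L)
})

test_that("training-mode stochasticity is seeded and absent at evaluation", {
    toy <- makeToyFixture()
    net <- toy_network()
    g <- induceSampleGraph(net, toy, sample = "s4")
    m <- initModel(small_model_config(), seed = 11)
    pay <- list(microGAT:::.graphPayload(g, 4L))
    run <- function(seed) withr::with_seed(seed,
        microGAT:::.gatBatchCpp(m@params, m@config, pay, 1, TRUE, FALSE)$loss)
    expect_identical(run(5), run(5))
    expect_false(identical(run(5), run(6)))
    # evaluation mode ignores the RNG entirely
    e1 <- withr::with_seed(5,
        microGAT:::.gatBatchCpp(m@params, m@config, pay, 1, FALSE, FALSE)$loss)
    e2 <- withr::with_seed(6,
        microGAT:::.gatBatchCpp(m@params, m@config, pay, 1, FALSE, FALSE)$loss)
    expect_identical(e1, e2)
})
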