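test_that("attention profiles live on the simplex with zero-sum CLR", {
    toy <- makeToyFixture()
    net <- toy_network()
    models <- list(initModel(small_model_config(), seed = 1),
                   initModel(small_model_config(), seed = 2))
    for (s in colnames(toy)) {
        pr <- attentionProfile(models, induceSampleGraph(net, toy, sample = s))
        expect_equal(sum(pr@attention), 1, tolerance = 1e-6)
        expect_equal(sum(pr@clr), 0, tolerance = 1e-6)
        expect_true(all(pr@attention > 0))
    }
    # single-node sample: attention 1, CLR 0
    ab <- c(g1 = 3, g2 = 0, g3 = 0, g4 = 0, g5 = 0, g6 = 0)
    g1 <- induceSampleGraph(net, ab, embeddings = genomicVectors(toy),
                            sample = "solo")
    pr <- attentionProfile(models, g1)
    expect_equal(unname(pr@attention), 1)
    expect_equal(unname(pr@clr), 0)
})

test_that("taxa ranking averages CLR attention and breaks ties lexically", {
    p1 <- new("AttentionProfile", sampleId = "a",
              attention = c(gB = 0.5, gA = 0.3, gC = 0.2),
              clr = c(gB = 0.4, gA = -0.1, gC = -0.3))
    p2 <- new("AttentionProfile", sampleId = "b",
              attention = c(gB = 0.6, gD = 0.4),
              clr = c(gB = 0.2, gD = -0.2))
    rk <- rankTaxa(list(p1, p2))
    expect_identical(rk$genus, c("gB", "gA", "gD", "gC"))
    expect_equal(rk$mean_clr_attention, c(0.3, -0.1, -0.2, -0.3))
    expect_identical(rk$n_samples, c(2L, 1L, 1L, 1L))
    # invariance to profile order
    expect_identical(rankTaxa(list(p2, p1))$genus, rk$genus)
    # tie-break: equal means sort lexicographically
    p3 <- new("AttentionProfile", sampleId = "c",
              attention = c(gZ = 0.4, gY = 0.4, gX = 0.2),
              clr = c(gZ = 0.1, gY = 0.1, gX = -0.2))
    rk3 <- rankTaxa(list(p3))
    expect_identical(rk3$genus, c("gY", "gZ", "gX"))
    expect_error(rankTaxa(list()), "no qualifying sample")
})

test_that("group stratification partitions by the sign of mean CLR", {
    rk <- data.frame(rank = 1:3, genus = c("g1", "g2", "g3"),
                     mean_clr_attention = c(0.5, 0, -0.2),
                     n_samples = c(3L, 3L, 3L))
    gr <- stratifyGroups(rk)
    expect_identical(gr$group_a, "g1")           # strictly positive only
    expect_identical(gr$group_b, c("g2", "g3"))  # zero goes to B
    expect_setequal(c(gr$group_a, gr$group_b), rk$genus)
    rk$mean_clr_attention <- c(0.5, 0.4, 0.1)
    expect_length(stratifyGroups(rk)$group_b, 0L)
})

test_that("interventions are seeded, bounded and no-ops at zero removals", {
    toy <- makeToyFixture()
    net <- toy_network()
    models <- list(initModel(small_model_config(), seed = 1))
    samples <- c("s1", "s2")
    r1 <- runIntervention(models, toy, samples, net,
                          group = c("g1", "g3", "g4"),
                          removalFraction = 0.5, nReps = 5, seed = 77)
    r2 <- runIntervention(models, toy, samples, net,
                          group = c("g1", "g3", "g4"),
                          removalFraction = 0.5, nReps = 5, seed = 77)
    expect_identical(r1, r2)
    expect_true(abs(r1$mean_delta) <= 1)
    expect_identical(r1$n_repetitions, 5L)
    # a group whose rounded removal count is zero leaves predictions alone
    r0 <- runIntervention(models, toy, samples, net, group = "g2",
                          removalFraction = 0.3, nReps = 3, seed = 1)
    expect_identical(r0$mean_delta, 0)
    expect_error(runIntervention(models, toy, samples, net, group = "g1",
                                 removalFraction = 1.2, nReps = 2, seed = 1),
                 "\\(0, 1\\)")
    expect_error(runIntervention(models, toy, samples, net,
                                 group = character(), removalFraction = 0.5,
                                 nReps = 2, seed = 1), "non-empty")
})

test_that("reports are written deterministically with full provenance", {
    rk <- data.frame(rank = 1:2, genus = c("gA", "gB"),
                     mean_clr_attention = c(0.2, -0.1),
                     n_samples = c(2L, 2L))
    iv <- data.frame(group = c("A", "B"), removal_fraction = c(0.5, 0.5),
                     mean_delta = c(-0.1, -0.01), p = c(0.02, 0.7),
                     n_repetitions = 100L, n_samples = 4L, seed = 1L)
    d <- withr::local_tempdir()
    paths <- writeReports(rk, iv, dir = d, provenance = list(seed = 1L))
    expect_true(all(file.exists(paths)))
    tab <- read.delim(file.path(d, "taxa_ranking.tsv"))
    expect_identical(nrow(tab), 2L)
    expect_identical(colnames(tab),
                     c("rank", "genus", "mean_clr_attention", "n_samples"))
    before <- tools::md5sum(paths)
    writeReports(rk, iv, dir = d, provenance = list(seed = 1L))
    expect_identical(tools::md5sum(paths), before)
})
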