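# microGAT

Graph attention networks over microbial co-expression networks, for
predicting a binary disease phenotype (atopic dermatitis vs. healthy
control) from genus-level gut-microbiome relative abundances — with
built-in interpretation of *which* genera drive each prediction.

## Who this is for

Microbiome researchers who have (i) a samples × genera relative-abundance
table (each sample summing to 100), (ii) binary phenotype labels, and
optionally (iii) a fixed-width genomic embedding vector per genus (e.g.
from a genome language model; treated as an opaque input). The package also
ships a synthetic-data generator with planted signal so every stage can be
exercised and validated without access-restricted clinical data.

## The method

1. **Compositional co-expression network.** Genus–genus correlations are
   computed on centered log-ratio (CLR) transformed samples
   (`clr(x) = ln(x / g(x))`, `g` = geometric mean) — a composition-adjusted
   (COAT-style) estimator. Stability selection draws five 80% subsamples
   and keeps edge `e_ij` only when `|c_ij| ≥ 0.1` with a consistent sign in
   every draw; the edge weight is the mean correlation.
2. **Sample graphs.** Each sample induces the subgraph over its non-zero
   genera. Node features concatenate the scalar abundance times a shared
   learnable 64-dim basis with the genus's genomic vector.
3. **GATv2 classifier.** Three graph-attention layers (8 heads, per-head
   width F; attention logits `aᵀ LeakyReLU(W[hᵢ‖hⱼ])`, softmax over
   neighborhoods with self-loops). Intermediate layers concatenate heads
   and apply Mish; the final layer averages heads. A self-attention readout
   projects node embeddings to scalars, softmaxes them into per-node
   attention scores `Aᵢ` (ΣAᵢ = 1), pools `P = Σ Aᵢ hᵢ`, and a two-hidden-
   layer MLP outputs the disease probability. Training: AdamW, binary
   cross-entropy, batch 16, 1% learning-rate decay every 10 epochs,
   60/20/20 stratified splits, early stopping on validation loss, and a
   five-seed probability-averaging ensemble.
4. **Interpretation.** Per-sample attention scores are CLR-normalized so
   they compare across samples; genera are ranked by mean CLR attention
   over correctly classified disease test samples; genera with positive
   mean CLR attention (Group A) vs the rest (Group B) are probed by an
   in-silico intervention that randomly removes 30/50/70% of a group 100
   times and measures the mean change in predicted probability.

The GATv2 forward/backward pass is implemented from scratch in
RcppArmadillo with analytic gradients (verified against numerical
differentiation in the tests); everything is exactly reproducible from
seeds.

## Worked example

```r
library(microGAT)

## synthetic two-class cohort: 300 samples, 60 genera, 10 discriminative
sim   <- generateDataset(simulationConfig(
             n_samples = 300, n_genera = 60, n_discriminative = 10,
             effect_size = 1.5, zero_inflation = 0.2, seed = 11))
mbe   <- sim$experiment                       # a MicrobiomeExperiment
net   <- buildNetwork(mbe, seed = 11)         # stability-selected network
net
#> CoexpressionNetwork: 60 genera, 81 edges (|c| >= 0.1, 5x80% subsamples, seed 11)

split  <- splitDataset(mbe, seed = 11)        # stratified 60/20/20
graphs <- sampleGraphs(net, mbe)
models <- trainEnsemble(graphs, sampleLabels(mbe), split,
             modelConfig(n_heads = 8, per_head_dim = 8, abundance_dim = 16,
                         genomic_dim = 32, mlp_hidden = c(16, 8)),
             trainConfig(learning_rate = 1e-3), seed = 101)

probs <- sapply(models, predictProb, graphs = graphs[split$test])
computeMetrics(rowMeans(probs), sampleLabels(mbe)[split$test])
#> $auroc [1] 0.9533333
#> $auprc [1] 0.9573319
#> $f1    [1] 0.8076923
```

The ensemble separates the classes almost perfectly (AUROC 0.95 on the 60
held-out samples) because ten genera carry a 1.5 log-unit abundance shift.
Interpretation recovers them:

```r
qual <- correctlyClassifiedDisease(models, graphs[split$test],
                                   sampleLabels(mbe))
rk   <- rankTaxa(lapply(qual, function(s) attentionProfile(models, graphs[[s]])))
head(rk, 3)
#>   rank genus mean_clr_attention n_samples
#> 1    1  g060          0.7605513        18
#> 2    2  g052          0.6156726        18
#> 3    3  g051          0.5732959        16
sum(sim$truth$discriminative %in% rk$genus[1:15])   # 8 of 10 planted genera
```

`g051`–`g060` are exactly the planted discriminative genera. Removing half
of them in silico (100 repetitions) drops the mean predicted disease
probability by ≈ 0.13, while removing a matched random control group
changes it by ≈ 0.01:

```r
ad <- split$test[sampleLabels(mbe)[split$test] == 1]
runIntervention(models, mbe, ad, net, sim$truth$discriminative,
                removalFraction = 0.5, nReps = 100, seed = 1)$mean_delta
#> [1] -0.1331791
```

A command-line front end over the same functions (subcommands `simulate`,
`network`, `train`, `predict`, `interpret`, `intervene`) is installed at
`inst/scripts/microgat-cli.R`.

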