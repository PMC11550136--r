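# promdiff

Generative design of fixed-length bacterial promoter sequences with a
**multinomial (categorical) diffusion model**, paired with a convolutional
sequence-to-expression regressor, planted-motif simulators, and an
evaluation suite for generated sequence sets. Everything runs on synthetic
data built by the package itself; no downloads are required.

The package is aimed at computational biologists who want a transparent,
fully-inspectable reference implementation of discrete diffusion for DNA:
every forward/backward pass, loss term and sampler step is ordinary matrix
algebra (hot paths in RcppArmadillo), pinned by exact oracles and
finite-difference tests.

## The model

A promoter of length $L$ over $\{A,C,G,T\}$ ($K=4$) is one-hot encoded.
The forward process resamples each base uniformly with probability
$\beta_t$ per step:

$$q(x_t\mid x_{t-1}) = \mathcal{C}\left(x_t \mid (1-\beta_t)x_{t-1} + \beta_t/K\right),
\qquad
q(x_t\mid x_0) = \mathcal{C}\left(x_t \mid \bar\alpha_t x_0 + (1-\bar\alpha_t)/K\right),$$

with $\bar\alpha_t = \prod_{\tau\le t}(1-\beta_\tau)$ decreasing to 0 at
$t=T$ (uniform terminal state). A block-local transformer predicts the
clean sequence $\hat x_0 = \mu(x_t, t)$; the reverse kernel is the exact
categorical posterior

$$q(x_{t-1}\mid x_t, x_0) \propto
 \left[\alpha_t x_t + (1-\alpha_t)/K\right]\odot
 \left[\bar\alpha_{t-1} x_0 + (1-\bar\alpha_{t-1})/K\right]$$

with $\hat x_0$ substituted for $x_0$. Training minimises the variational
bound $L = E\{-\log p(x_0|x_1) + \sum_{t\ge2}
KL[q(x_{t-1}|x_t,x_0)\,\|\,q(x_{t-1}|x_t,\hat x_0)]\}$, by default
complemented with the standard auxiliary denoising cross-entropy for
discrete diffusion (see the methods vignette for why). Sampling starts
from i.i.d. uniform bases and runs the reverse chain.

Generated candidates are scored by a 1D-CNN regressor (conv channels
100-200-200-10, kernel 5, batch norm + ReLU, global max-pool, linear
head) trained on (sequence, expression) pairs with early stopping on
validation Pearson correlation.

## Worked example

```r
library(promdiff)

# a synthetic promoter-like corpus with noisy expression labels:
# -35 and -10 boxes, spacer ~ N(17, 1), labels = motif scores + noise
bench <- synth_promoter_benchmark(n = 2000, seed = 1)

# where do the -35/-10 boxes sit relative to each other?
boxes <- bench$pfms
imd <- inter_motif_distances(bench$sequences, boxes$minus35, boxes$minus10)
imd$mode
#> [1] 17

# train a small diffusion model and sample novel sequences
fit <- mdm(bench$sequences, T_steps = 20, layers = 2, heads = 4,
           embed_dim = 64, local_size = 50, epochs = 10,
           batch_size = 16, lr = 1e-3, seed = 1)
samples <- simulate(fit, nsim = 500, seed = 2)

# how faithful are the samples?
kmer_pearson(samples, bench$sequences)   # 6-mer frequency correlation
gc_js_divergence(samples, bench$sequences)  # GC-content JS divergence (bits)
min_edit_diversity(samples, subsample = 500) # mean min. edit distance

# score candidates with the CNN predictor and keep the best
cnn <- expr_cnn(bench$sequences, bench$expression,
                conv_channels = c(32, 64, 64, 10), batch_size = 32,
                epochs = 100, lr = 2e-3, patience = 50, seed = 3)
round(cnn$test_pearson, 2)
#> [1] 0.85  # motif-score signal with 20% label noise; scan-oracle ~ 0.89
preds <- data.frame(sequence = samples,
                    prediction = predict(cnn, samples))
head(select_top(preds, 24))
```

The motif-pair *decoupling* benchmark plants ordered motif pairs with a
13-bp spacer into random 50-bp templates (six PFMs give 36 combinations,
1,000 sequences each):

```r
pfms <- lapply(list.files(system.file("extdata", package = "promdiff"),
                          full.names = TRUE), read_jaspar_pfm)
ds <- build_pair_dataset(pfms, per_pair = 1000, seed = 0)
nrow(ds)                        # 36000
gd <- gap_distribution(ds$sequence[ds$pair_id == ds$pair_id[1]],
                       pfms[[1]], pfms[[1]])
gd$mode                         # 13
```

`decoupling_heatmap()` scores how well a generator preserved each pair's
spacer grammar via $val = -\log_2 H(dist_{gen}, dist_{ori})$.

An end-to-end pipeline (train, sample, predict, evaluate, manifest) is
available as `run_pipeline()`, with a thin command-line front end at
`inst/cli/promoter-mdm.R`.

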