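# seq2expr

Modeling and rational design of short regulatory DNA from gigantic
parallel reporter assays (GPRA), in R.

In a GPRA, millions of short random promoter inserts (typically 80 bp)
drive a fluorescent reporter in yeast; cells are sorted into 18
fluorescence bins (numbered 0–17) and a sequence's expression is the
weighted average of the bin numbers where its cells were observed. Most
sequences are "singletons" seen in a single cell, so their expression is
an integer and noisy. `seq2expr` is for computational biologists who want
to learn this sequence-to-expression map, estimate the effect of
single-nucleotide variants, and design new promoters with a requested
expression level — all from plain TSV tables of sequences and
expressions.

## The model

The scalar regression is recast as **soft classification** over the 18
sorting bins. A measured expression *e* is assumed to arise from a latent
expression distributed N(μ = e + 0.5, σ = 0.5); bin *i* ∈ {1..16}
receives the probability mass of [i, i+1) and bins 0 and 17 absorb the
full tails, so the 18-vector sums to one exactly. Training minimizes
KL(target ‖ model output); a scalar prediction is decoded by
**soft-argmax**, ê = Σᵢ i·pᵢ.

The network is fully convolutional, in the EfficientNetV2 family: a
kernel-7 stem (256 channels, BatchNorm, SiLU), six blocks of widths 128,
128, 64, 64, 64, 64 — each an expansion pointwise convolution, a
grouped (or depthwise) kernel-7 convolution, a squeeze-and-excitation
gate (the original variant stores its bilinear first stage as a rank-21
CP-factorized tensor), a pointwise projection, then **residual
channel-wise concatenation** fused by a kernel-7 resize convolution — and
a pointwise head with global average pooling and softmax. The stride-1
stack has a 79-bp receptive field and the original configuration has
exactly 1 852 846 trainable parameters. Inputs are 6×150 matrices: 4
one-hot nucleotide channels over the 5'-flank-padded 150-bp frame plus
constant `is_singleton` and `is_reverse` channels; training augments with
reverse complements and prediction averages both orientations.

Variant effects are prediction differences, Δ = ê(alt) − ê(ref). A
**cold-diffusion generator** (the same trunk with a per-position 4-way
head, conditioned on a mutation count and a target expression through
two extra input channels) designs sequences by iteratively denoising a
random 80-mer with a shifted re-corruption schedule (100 iterations,
shift 30 by default).

Because full-scale GPRA training is GPU-scale, the package bundles a
**synthetic GPRA simulator** (planted PWM grammar, sorting-bin
measurement model with realistic singleton structure) that provides
ground truth for desk-scale validation of the whole stack. The neural
network, its backward passes and the optimizers (AdamW, Lion; one-cycle
cosine schedule) are implemented in the package itself with
RcppArmadillo/BLAS compute kernels — see the methods vignette
(`vignettes/sequence-to-expression.Rmd`) for the architecture knobs,
numerical choices and desk-scale problem sizes.

## Worked example

```r
library(seq2expr)

# simulate a desk-scale GPRA: 20 000 training rows, 2 000 test rows
cfg  <- simulator_config(n_sequences = 20000, n_test = 2000, seed = 1)
data <- simulate_dataset(cfg)
head(data$train, 3)

# train a small predictor (80-bp frame: the simulated inserts are flankless)
flank <- flank_context(strrep("N", 80), frame = 80)
tc    <- train_config(batch_size = 128, batches_per_epoch = NULL,
                      epochs = 3, seed = 1)
fit   <- train_predictor(data$train, tc, tiny_config(), flank)
fit$log

# held-out accuracy against the simulator's oracle
truth <- subset(data$truth, split == "test")
pred  <- predict_with_tta(fit$model, data$test$insert, flank)
bootstrap_correlations(pred$expression, truth$oracle, seed = 1)

# effect of a single substitution
v <- variant_record(data$test$insert[1], 40L,
                    substr(data$test$insert[1], 41, 41), "A")
variant_effect(fit$model, v, flank)
```

A run of this example prints (abridged):

```
  epoch mean_loss          lr   wall
1     1  1.876795 0.004974402 26.888
2     2  1.577171 0.002321379 26.306
3     3  1.426804 0.000000500 25.516
<evaluation_report> n = 2000, 10000 resamples (0 degenerate)
  Pearson  0.7307  [0.7098, 0.7503]
  Spearman 0.7216  [0.6978, 0.7439]
[1] 0.6665047
```

The epoch log shows the KL loss falling under the one-cycle schedule; the
bootstrap report gives the held-out Pearson/Spearman correlation between
predicted and oracle expression with 95% percentile intervals (this short
3-epoch run reaches ~0.73; the package's acceptance study at 50 000 rows
and 5 epochs reaches ~0.96); the final number is the predicted expression
change (in bin units) caused by the substitution — here the alternative
allele raises predicted expression by about 0.67 bins.

Promoter design follows the same pattern with `train_generator()`,
`generate_promoters()` (argmax or posterior-sampling decode) and
`score_designs()`; a thin command-line wrapper over these functions is
installed at `inst/cli/seq2expr.R`
(`simulate / train / predict / variant-effect / train-generator /
generate / evaluate`).

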