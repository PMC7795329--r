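# sstgcn

Emotion recognition from 3D body-skeleton sequences with a two-stream
self-attention enhanced spatial-temporal graph convolutional network.

## What it does

Given short clips of upper-body joint trajectories — `T` frames, `V = 10`
joints, xyz coordinates, as produced by video pose estimation — the
package classifies the expressed emotion (neutral, happy, sad, angry).
The skeleton is modeled as a graph (joints = vertices, bones = edges) and
features are propagated by spatial-temporal graph convolutions, with two
additions in the spatial layer:

- a **graph-convolution branch**: `f_g = Σ_k f_k (A_k ⊗ M_k)`, where the
  adjacency is split into K = 3 subsets `A_k` by the spatial-configuration
  partitioning (root / centripetal / centrifugal with respect to the
  body-center joint) and `M_k` are trainable edge masks;
- an **attention branch**: per frame, multi-head scaled dot-product
  self-attention over the joints, `e_ij = (a_i W_Q)(a_j W_K)ᵀ / √d_k`,
  `α_ij = softmax_j(e_ij)`, `s_i = Σ_j α_ij (a_j W_V)`, heads concatenated
  and projected by `W_O`, plus a residual — connections the fixed skeleton
  does not provide;

combined by a trainable per-layer gate, `f_out = (f_g + r·f_a)/2` with
`r` initialized at 1. Ten such blocks (output channels
32,32,32,32,64,64,64,128,128,128) alternate with temporal convolutions of
receptive field `(K_t, 1)`; global average pooling and a softmax output
layer produce class probabilities. Two networks are trained — one on
joint coordinates, one on **bone vectors** (`v_child − v_parent` toward
the body center) — and their softmax scores are fused by summation or by
a trained fully connected layer. Evaluation reports the unweighted
average recall (UAR, mean per-class recall) and the weighted average
recall (WAR, accuracy).

The package also contains the full experimental plumbing: zero-phase
Butterworth low-pass filtering of joint trajectories, joint subsetting
and length standardization, deterministic stratified 8 : 0.5 : 1.5
splits, a seeded training loop (SGD with momentum, cross-entropy,
best-dev-UAR checkpointing), a class-conditional synthetic
skeleton-sequence generator, and a command-line wrapper
(`inst/cli/sstgcn`) with `simulate`, `preprocess`, `train`, `eval` and
`fuse` subcommands. Everything runs on one CPU; the network forward and
backward passes are implemented in R with small C++ kernels.

## Worked example

Generate a synthetic dataset, preprocess it, train both streams and fuse
them — this is the packaged reference experiment:

```r
library(sstgcn)
res <- run_synthetic_benchmark(seed = 0, fit_fc_head = TRUE)
res$report_joint
#> eval_report: UAR 0.883, WAR 0.883
#>         angry happy neutral sad
#> angry       8     0       7   0
#> happy       0    15       0   0
#> neutral     0     0      15   0
#> sad         0     0       0  15
c(joint = res$uar_joint, bone = res$uar_bone,
  fused = res$uar_fused_sum, fused_fc = res$uar_fused_fc)
#>     joint      bone     fused  fused_fc
#> 0.8833333 0.8500000 0.8666667 0.9833333
```

The numbers are test-set UARs on 60 held-out samples (15 per class):
each stream alone recognizes the four synthetic emotion signatures well
above the 0.25 chance level, and fusing the streams' scores combines
their strengths. Step by step, the same experiment is:

```r
graph <- build_upper_body_graph()                 # 10 joints, 9 edges
ds    <- generate_dataset(generator_spec(seed = 0))
clean <- preprocess_dataset(ds, filter_config(),  # 6 Hz zero-phase filter
                            length_policy(64))    # resample to 64 frames
sp    <- split_dataset(clean, split_spec(seed = 0))   # 320 / 20 / 60
model <- sstgcn(model_config(channels = c(16, 16, 32, 32),
                             strides = c(1, 2, 1, 2),
                             temporal_kernel = 5, t_fix = 64),
                graph, seed = 0)
fit   <- train_model(model, sp$train, sp$dev, epochs = 6, lr = 0.02,
                     seed = 0)
evaluate(fit$model, sp$test)
```

## Scientific background

The methods vignette (`vignettes/sstgcn-methods.Rmd`) documents the
model, its assumptions, all tunable parameters with defaults and units,
what the synthetic generator does and does not emulate, and the
package's numerical choices.
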