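---
title: "Low-rank attention autoencoders for ECG classification: model, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-rank attention autoencoders for ECG classification: model, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lraecg)
```

## The model

`lraecg` classifies fixed-length ECG beat segments in three stages: a
parameter-free attention block over feature dimensions, a tanh autoencoder
weighted by that attention at every encoder layer, and a one-dimensional
ResNet-18 on the latent features.

### Low-rank dimension attention

For a batch `X` of n beats by d samples, the attention block computes the
Gram matrix `G = XᵀX`, its SVD `G = U diag(S) Vᵀ`, the matrix product `UV`,
and double-normalizes it into a row-stochastic d×d matrix: a column-wise
softmax followed by a row-wise sum normalization (`double_norm()`). Three
properties matter in practice:

* **`UV`, not `UVᵀ`.** `G` is symmetric positive semi-definite, so its right
  singular vectors equal its left ones and `UVᵀ` collapses to the identity —
  an attention matrix independent of the input. The matrix product `UV` is
  the reading that keeps the attention input-dependent; `lra_weights()`
  exposes `product = "UVt"` purely for comparison.
* **Sign convention.** Singular vectors are determined only up to matched
  sign flips, and `UV` changes under them. `lra_weights()` therefore negates
  each column pair whose largest-magnitude `U` entry (ties: lowest row
  index) is negative. For non-degenerate spectra this makes the output
  backend-independent; for repeated or zero singular values (e.g. a
  rank-deficient Gram matrix when n < d) no uniqueness exists and the
  contract is only determinism for a fixed SVD backend. The test suite
  restricts oracle comparisons to full-rank cases for exactly this reason.
* **Scale invariance.** Singular vectors of `c²G` equal those of `G`, so
  the attention matrix is invariant to positive rescaling of `X`.

Because `U` and `V` are orthogonal, `UV` is itself orthogonal: its entries
are O(1/√d), so after double normalization the attention matrix is always a
modest perturbation of the uniform matrix `1/d`. Applying it (`X %*% A`) is
therefore a structured smoothing of each beat, not a sparse selection — a
property with consequences for data scaling discussed below.

### The gradient-isolation contract

Attention matrices participate in the forward value only. Every gradient
in this package is hand-derived, and the backward pass maps the gradient
arriving at a weighted input `O %*% A` back through `t(A)` alone — the
dependence of `A` on `O` through the SVD is deliberately excluded, keeping
the extracted spatial weights fixed data rather than trainable quantities.
The tests verify both directions: the implemented gradient agrees with
finite differences of a surrogate in which `A` is frozen (relative
tolerance 1e-4), and it *disagrees* with finite differences of the full
path through the SVD.

### Autoencoder

Three encoder layers (defaults d = 250 → 128 → 96 → 64) and two decoder
layers (64 → 128 → d), all tanh. Each encoder layer recomputes attention on
its own current input every forward pass — the weights follow the
activations as training progresses, they are not cached from epoch 0.
Training minimizes mean squared reconstruction error with full-batch Adam
(learning rate 1e-3, 200 epochs by default; minibatches configurable).
Because the final tanh bounds reconstructions in (−1, 1) while Z-scored
signals exceed that range, training data are affinely mapped into
[−0.95, 0.95] per dataset first (the map is stored and invertible); a
`final_activation = "linear"` option removes the need. The duplicated
third line in some statements of the five-layer architecture is read as a
typesetting artifact: three encoder layers, two decoder layers.

Adam is not monotone: on the 32-beat overfit fixture the loss falls from
≈0.20 to ≈0.03 within 50 epochs and then oscillates at the plateau, so
roughly 70% of epoch-to-epoch transitions are non-increasing overall
(≈85% during the descent). Tests assert the envelope behaviour rather than
strict monotonicity.

### 1D ResNet-18 head

The latent `O³` (length 64) enters as a single-channel sequence. The stem
applies two kernel-3, stride-3, padding-0 convolutions (1 → 3 → 64
channels; 64 → 21 → 7 positions), batch normalization and ReLU. Four
stages of two basic blocks follow with channels 64/128/256/512. Inside a
block every convolution is kernel 3, stride 1, padding 1, and the block
output is `F(x) + x` with `F` = conv → batch-norm → ReLU → conv →
batch-norm → ReLU. Keeping all block convolutions at stride 1 conflicts
with any downsampling, so stride-2 downsampling sits at the entry of
stages 2–4 with 1×1 projection shortcuts — the standard ResNet placement —
while a `no_downsample` switch preserves the literal all-stride-1 reading.
Four "ResBlocks" are reconciled with ResNet-18's eight basic blocks by
reading them as the four stages. Global average pooling and a fully
connected layer produce 4-class scores; softmax gives reported
probabilities; argmax ties resolve to the lowest class index. The default
configuration has 3,850,896 parameters (regression-tested).

Convolutions are computed by im2col + BLAS matrix multiplication with
hand-derived backward passes; batch normalization uses biased batch
variance, momentum 0.1 running statistics and variance floor eps = 1e-5
(train mode uses batch statistics, eval mode the running ones). Classifier
training uses minibatch Adam (default batch 128, learning rate 1e-3) on
cross-entropy; an `mse_one_hot` loss matches the letter of an MSE objective
stated over categories, which for the autoencoder itself is read as signal
reconstruction — the only self-supervised interpretation consistent with an
autoencoder. Training is staged by default (pretrain, then classify);
`joint_training = TRUE` optimizes the summed reconstruction and
classification losses in one phase.

A practical note on batch normalization and small runs: running statistics
start at (0, 1) and converge geometrically (factor 0.9 per step), so
eval-mode behaviour is only trustworthy after on the order of 100 optimizer
steps. The default study conditions (800 training beats, batch 128, 30
epochs ≈ 210 steps) satisfy this comfortably; very small demonstration runs
should shrink the batch size or raise the epoch count accordingly.

## Preprocessing conventions

* Z-score standardization uses the **population** standard deviation
  (divisor n), switchable to the sample divisor; constant signals return
  zeros with a warning rather than dividing by zero.
* Standardization is **per record**, not per beat: segments cut by
  `segment_beats()` keep the baseline and amplitude differences between
  beats of the same record.
* All indices are 0-based and all windows half-open `[start, end)`, across
  the loaders, the segmenter and the generators. The default beat window is
  100 samples before and 150 after the R peak (250 samples ≈ 0.69 s at
  360 Hz); the targeted beat symbols are N, L, R, V, with everything else
  filtered and counted.
* Variable-length single-label records are Z-scored, then truncated from
  the start or zero-padded at the end to a fixed length (default 9000 =
  30 s × 300 Hz), with statistics computed before padding.
* WFDB reading (header, format 212/16 signals, MIT-format annotations) is
  implemented directly in R against the published format description, since
  no WFDB reader package is available; it is read-only and covers the
  subset those archives use.

## The synthetic generator

Each beat class is a sum of Gaussian bumps (amplitude mV, center s, width
s) plus white Gaussian noise, with presets in
`inst/extdata/presets.yaml`: N has the full P-QRS-T complex; L a wide
notched QRS (two merged R bumps) and discordant T; R an rsR′ double peak;
V no P wave and a main peak at least 1.5× the width of N's. Rhythm strips
place beats at RR intervals drawn per class — regular sinus (Gaussian
jitter, sd 0.02 s), atrial fibrillation (uniform jitter of half-width
0.25 s around 0.70 s and zero P amplitude, giving an RR coefficient of
variation several times sinus), a slow wide-complex "Other" class, and a
"Noisy" class whose additive noise (sd 0.5 mV) pushes the signal-to-noise
ratio below 0 dB. Generators store their internals (RR list, clean and
noise components, R-peak indices) so the tests can verify these as
measurable post-conditions rather than intentions.

`synth_beat_dataset()` standardizes the generated collection with its
**pooled** mean and population standard deviation — the record-level
convention — rather than per beat. This is deliberate: per-beat Z-scoring
forces every row to zero mean and unit variance, and because the LRA
attention matrix is a near-uniform smoother, the encoder then shrinks
sample-to-sample variation by roughly 1/d per layer; latent features
collapse toward a constant and the classifier's batch-norm statistics
cannot track the residual scale. Pooled standardization preserves exactly
the per-beat offset and energy information that record-level Z-scoring
preserves for real recordings, and is what makes the latent space
class-separable at a numerically healthy scale.

What the generator does *not* emulate: baseline wander, powerline
interference, electrode artifacts, inter-patient morphology variability,
class imbalance, or physiologically validated waveshapes (it is a
Gaussian-bump model, not a dynamical simulator). A pipeline that classifies
these synthetic classes perfectly demonstrates that the implementation is
correct and that the architecture can learn separable morphologies — it
does not demonstrate clinical-grade performance on real arrhythmia data,
whose replication additionally depends on record selection and splitting
choices that published evaluations often leave unspecified.

## Problem sizes and determinism

The shipped study conditions are 200 training and 80 held-out beats per
class (seeded stratified split of a 280-per-class collection), 200
autoencoder epochs, and up to 30 classifier epochs — sizes at which the
full pipeline trains in a few minutes on one core while leaving every
stage's behaviour measurable. Every random choice (generation, splitting,
initialization, batch order) derives from a single integer seed through
scoped RNG state, so a (config, seed) pair reproduces the evaluation
report, and its hash, exactly; model checkpoints round-trip bit-exactly
through R's native serialization.

## Known limitations

* The attention matrix is d×d and the SVD O(d³); beats of a few hundred
  samples are cheap, but the block is not intended for very long windows.
* For rank-deficient Gram matrices the attention output is
  backend-deterministic, not mathematically unique (see the sign-convention
  discussion).
* Pure-R training is practical at study scale (minutes) but not at the
  scale of full multi-hour archives; the package's value there is as a
  verifiable reference, with the same contracts, rather than a speed claim.
* Replicating published accuracies on the real MIT-BIH / single-lead
  challenge archives requires the original record and beat selection and
  split protocol, which are not fully specified; the loaders and CLI accept
  explicit record lists so such replications remain best-effort scripts
  rather than promised numbers.
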