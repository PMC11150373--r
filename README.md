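# lraecg

Electrocardiogram (ECG) beat classification with a **low-rank attention
autoencoder** and a **1D ResNet-18** head, implemented end to end in R with
hand-written backpropagation — no deep-learning framework required.

## Who this is for

Researchers and engineers working on automated arrhythmia screening who want
a transparent, fully reproducible reference implementation of SVD-based
dimension attention for physiological time series: every forward pass,
gradient and optimizer step is plain R code that can be read, instrumented
and unit-tested. A seeded synthetic ECG generator makes the whole pipeline
runnable and testable with no data download; readers for WFDB
(`.hea`/`.dat`/`.atr`) and a plain-text CSV fixture dialect connect it to
real recordings.

## The method

Given a feature matrix `X ∈ R^{n×d}` (n beats, d samples per beat), the
**low-rank attention (LRA) block** derives a d×d attention matrix over
feature dimensions from the singular value decomposition of the Gram matrix:

```
(U, S, V) = svd(XᵀX)
A = Norm(U V)
```

where `Norm` is **double normalization**: a column-wise softmax
`ã_ij = exp(ā_ij) / Σ_i exp(ā_ij)` followed by row-wise sum normalization
`a_ij = ã_ij / Σ_j ã_ij`, so every row of `A` is a probability vector.
Unlike query/key self-attention (`softmax(QKᵀ/√d_k)·V`, also provided for
reference), the LRA weights capture correlation between *feature dimensions*
rather than between samples, and contain no trainable parameters.

The **LRA autoencoder** applies a fresh attention matrix at every encoder
layer:

```
O¹ = tanh(W₁(X F(X)) + b₁)
O² = tanh(W₂(O¹ F(O¹)) + b₂)
O³ = tanh(W₃(O² F(O²)) + b₃)        # latent features
O⁵ = tanh(W₅ tanh(W₄ O³ + b₄) + b₅) # reconstruction
```

with the **gradient-isolation contract**: `F(·)` enters the forward value
only; backpropagation treats every attention matrix as a constant, so no
gradient flows through the SVD. The autoencoder is pretrained with Adam on
mean-squared reconstruction error; the latent `O³` then feeds a 1D-adapted
ResNet-18 (stem of two kernel-3/stride-3 convolutions taking 1→3→64
channels, four stages of two basic residual blocks with 64/128/256/512
channels and `F(x) + x` outputs, global average pooling, 4-class output).
Evaluation reports one-vs-rest precision, recall, `F₁ = 2PR/(P+R)` and
overall accuracy from the confusion matrix.

## Worked example

```r
library(lraecg)

ds <- synth_beat_dataset(n_per_class = 50, seed = 1)
print(ds)

res <- train_pipeline(run_config(n_train_per_class = 40, n_test_per_class = 10,
                                 ae_epochs = 100, clf_epochs = 25,
                                 clf_batch_size = 32, seed = 1))
print(res$autoencoder)
print(res$classifier)
print(res$report)
```

prints (about 40 s on one core):

```
<beat_dataset>  200 segments x 250 samples
  classes: N=50, L=50, R=50, V=50
<lra_autoencoder>  250 -> 128 -> 96 -> 64 -> 128 -> 250, 100 epochs trained
  reconstruction MSE: 0.19433 (first) -> 0.03454 (final)
<resnet1d>  in_length 64, channels 64/128/256/512, 4 classes, 3850896 parameters
  cross_entropy loss: 0.8230 (first epoch) -> 0.0015 (final)
Confusion matrix (rows = true, columns = predicted):
    predicted
true  N  L  R  V
   N 10  0  0  0
   L  0 10  0  0
   R  0  0 10  0
   V  0  0  0 10

Class     Precision     Recall         F1
N             1.000      1.000      1.000
L             1.000      1.000      1.000
R             1.000      1.000      1.000
V             1.000      1.000      1.000
Overall accuracy: 1.000
```

The dataset holds four synthetic beat classes mirroring the MIT-BIH target
labels — normal (N), left/right bundle branch block (L/R) and premature
ventricular contraction (V) — standardized with the pooled record-level
Z-score. The autoencoder compresses each 250-sample beat to a 64-dimensional
latent (reconstruction MSE falls from 0.194 to 0.035 on the tanh-mapped
scale); the classifier separates the held-out beats perfectly, so every
one-vs-rest precision/recall/F1 cell is 1 and the accuracy is 1.000.

A command-line interface wrapping the same functions lives at
`inst/cli/lraecg.R` (subcommands `simulate`, `pretrain`, `train`,
`evaluate`, `predict`, `attention-dump`, each taking `--config file.yaml`
and `--seed`).

## Package layout

| Area | Functions |
| --- | --- |
| Attention | `self_attention`, `simplified_self_attention`, `double_norm`, `lra_weights`, `apply_lra_weighting` |
| Autoencoder | `ae_config`, `init_autoencoder`, `ae_encode`, `ae_decode`, `pretrain_autoencoder`, `latent_features` |
| Classifier | `classifier_config`, `init_classifier`, `classifier_forward`, `res_block_forward`, `relu`, `train_classifier`, `predict` |
| I/O & preprocessing | `load_record`, `read_wfdb_record`, `zscore`, `segment_beats`, `prepare_fixed_length`, `write_fixture` |
| Synthetic data | `beat_morphology`, `default_morphologies`, `synth_beat`, `synth_beat_dataset`, `rhythm_spec`, `synth_rhythm_record` |
| Pipeline & metrics | `run_config`, `train_pipeline`, `evaluate_model`, `class_metrics`, `f1_score`, `write_report`, `report_hash`, checkpoints |

The methods vignette (`vignettes/lra-autoencoder-methods.Rmd`) documents the
model, its numerical choices, the synthetic generator's assumptions and the
known limitations.
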