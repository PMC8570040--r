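---
title: "Generalizable and discriminative training for motor-imagery EEG decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalizable and discriminative training for motor-imagery EEG decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Subject-dependent motor-imagery (MI) brain–computer interfaces decode which
movement a user imagines from a few hundred labeled EEG trials. Two
properties of this data shape everything in this package: the
signal-to-noise ratio is low (scalp EEG mixes a few-microvolt sensorimotor
rhythm into a large 1/f background), and the training sets are small (a
session yields on the order of 100–300 trials). Convolutional networks
trained with the plain cross-entropy respond to this combination in a
well-known way: they grow overconfident, memorize noisy trials, and produce
penultimate-layer features that are merely *separable* rather than
*discriminative* — classes sit on the correct side of the decision boundary
but spread widely.

`micnn` implements a training scheme that attacks both failure modes at
once, by changing the objective rather than the architecture:

\[
L \;=\; L_{cl} \;+\; \alpha_{lsr}\,L_{lsr} \;+\; \alpha_{ct}\,L_{ct}
\]

* \(L_{cl} = -\sum_i \log q_\theta(y_i \mid x_i)\) is the usual
  cross-entropy of the softmax outputs against the one-hot labels.
* \(L_{lsr} = \sum_i H_i(u, q_\theta)\) is the **label-smoothing
  regularizer**: the cross-entropy of each prediction against the uniform
  distribution \(u = 1/M\). Weighting it by \(\alpha_{lsr}\) is algebraically
  identical to training against smoothed targets
  \(p' = (1-\varepsilon)\,p + \varepsilon u\) with
  \(\varepsilon = \alpha_{lsr}/(1+\alpha_{lsr})\) (up to the overall factor
  \(1-\varepsilon\)); `smoothed_cross_entropy()` exposes both forms and the
  test suite checks their agreement to 1e-10. Smoothing caps the confidence
  a prediction can profitably reach, which is what prevents the memorization
  of corrupted labels.
* \(L_{ct} = \tfrac12 \sum_i \lVert x_i - c_{y_i} \rVert_2^2\) is the
  **center loss** on the flatten-layer ("deep") features: each class keeps a
  running center \(c_j\), and features are pulled toward their class center.
  The cross-entropy pushes classes apart; the center loss pulls each class
  together; jointly they produce features with large inter-class distance
  and small intra-class variance.

Centers are *state*, not parameters: the gradient of \(L_{ct}\) flows into
the features only, and centers move through their own damped update,
\(c_j \leftarrow c_j - \alpha_c \sum_{i:y_i=j}(c_j - x_i)/(1+n_j)\), whose
fixed point is the class mean. We apply this update after every mini-batch
(the established practice for this loss, and the stabler choice at our
sample sizes) with \(\alpha_c = 0.5\); a per-epoch mode, which matches a
strictly epoch-level reading of the construction, is available through
`train_config(center_update_mode = "per_epoch")`.

All losses are mean-reduced over the batch by default, so loss magnitudes
are comparable across batch sizes; a `reduction = "sum"` mode exists for
verifying the printed sum-form equations. Both modes satisfy the same
identities.

## The network

The classifier is a compact three-block CNN in the EEGNet family, operating
on raw trials of `E` electrodes by `T` samples:

| stage | operation | output shape (time, space, channels) |
|---|---|---|
| input | — | (T, E, 1) |
| 1 | temporal conv, `F1` filters, kernel (`K1`, 1), same padding + BN | (T, E, F1) |
| 2 | depthwise conv, kernel (1, `E`), multiplier `D` + BN + ELU + avg-pool (`P1`, 1) | (T/P1, 1, F1·D) |
| 3 | separable conv, `F2` filters, kernel (`K2`, 1), same padding + BN + ELU + avg-pool (`P2`, 1) | (T/(P1·P2), 1, F2) |
| 4 | flatten | T·F2/(P1·P2) |
| 5 | dense + softmax | M |

Defaults are `F1 = 8`, `F2 = 16`, `K1 = 32`, `K2 = 16`, `D = 2`,
`P1 = P2 = 8`. The short temporal kernel (32 samples = 128 ms at 250 Hz)
biases the first stage toward content above ~8 Hz, where the mu (8–12 Hz)
and beta (12.5–30 Hz) rhythms that carry the MI signal live. The flatten
activations are the "deep features" regularized by the center loss and
inspected by the PCA/dispersion tools.

Because average pooling here is exact (no remainder handling), a buildable
configuration needs `T` divisible by `P1` and `T/P1` divisible by `P2`.
Note that the conventional 4-s, 1000-sample window *fails* this with
`P1 = P2 = 8` (1000/8 = 125, and 125/8 is not integral): a framework with
floor-division pooling would silently drop samples, whereas
`validate_divisibility()` rejects the configuration. `feature_dim()`
evaluates the flatten formula itself (it only requires the final quotient to
be integral, so `feature_dim(model_config(T = 1000, E = 22, M = 4))` is
250); shape-conformance tests use `T = 960`, the nearest window length that
satisfies both stage constraints, and our 500-sample synthetic benchmark
uses `P1 = 5`, `P2 = 10`.

Choices the architecture description leaves open, fixed here once:

* no bias terms in convolutions that feed a batch norm; dense layer has a
  bias;
* ELU with \(\alpha = 1\); batch-norm momentum 0.99, epsilon 1e-3;
* "same" zero padding in the temporal and separable convolutions (the only
  assignment consistent with the printed output shapes); none in the
  depthwise stage, which collapses the electrode axis;
* no dropout and no max-norm constraint by default — the printed stack lists
  neither, although the parent architecture family uses both; both are
  available as opt-in arguments to `build_model()`/`train_model()`;
* flatten order is time-fastest within each channel map (any fixed order
  works; this one matches the internal memory layout);
* argmax prediction resolves exact ties to the lowest class index;
* Glorot-uniform initialization, deterministic given the seed.

The forward/backward engine is written in RcppArmadillo. Batch
normalization uses biased batch variance in training and running statistics
(momentum 0.99) in inference; the softmax subtracts the row maximum before
exponentiation; predicted probabilities are floored at 1e-12 inside logs.
The full backward pass is verified against central finite differences in
the test suite (worst relative error around 1e-9 on a small
configuration). Every kernel is deterministic, so a fixed seed reproduces
training bitwise.

## Training loop

`train_model()` follows the standard recipe for this model family: Adam
(moments 0.9/0.999, epsilon 1e-8) at learning rate 0.001, mini-batches of
64, 750 epochs, loss weights \(\alpha_{lsr} = \alpha_{ct} = 0.5\) — all
overridable through `train_config()`. The last incomplete batch of an epoch
is kept; batch size 1 is rejected because batch norm needs batch
statistics. Per epoch the history records the training losses and accuracy
as the trial-weighted mean over that epoch's training-mode batches (the
convention of mainstream deep-learning histories) and the test metrics from
a full inference pass. The test set is *monitored*, never used for early
stopping or model selection; the final-epoch model is returned.

`run_ablation()` retrains the model once per grid value of
\(\alpha_{lsr}\) or \(\alpha_{ct}\), everything else (including the seed)
held fixed, and tabulates final test accuracy together with the final
standard test cross-entropy — the one generalization measure that remains
comparable across models trained with different objectives.

## The synthetic benchmark

Real MI recordings require a download and hours of training, so the package
ships a generator whose trials carry the same discriminative physics at a
controllable strength. Each trial is a sum of three parts per channel:

* a sensorimotor rhythm `rhythm_amp * (sin(2π f_mu t + φ) + 0.5 sin(2π
  f_beta t + ψ))` with fresh random phases per trial and channel
  (defaults: 10 and 20 Hz, 10 µV);
* pink (1/f-power) background noise generated by inverse-FFT spectral
  shaping, scaled to 5 µV RMS;
* white sensor noise, 2 µV SD.

Class identity enters only through **event-related desynchronization**:
class `j` attenuates the rhythm multiplicatively, by the factor
`1 - rho * pattern[j, e]`, on its own binary channel subset
(`make_spatial_patterns()`; rows distinct, each class affecting at least one
channel). This puts the class signal exactly where MI physiology puts it —
in band power, not in additive waveform templates — so a model must learn a
spectral-spatial contrast to solve the task. `rho` is the single
separability dial: at `rho = 0` classes are statistically identical (a
classifier must sit at chance), at `rho = 1` affected channels lose the
rhythm entirely. `band_power()` (periodogram integral) is the oracle the
tests use to verify all of this, including the monotone decrease of mu-band
power in `rho`.

The amplitude defaults were chosen once for realism of scale (a ~10 µV
rhythm over a ~5 µV background is a typical scalp EEG regime) and are not
tuned per experiment. Sessions are generated balanced and shuffled, fully
determined by `seed`; the class-to-channel patterns take a separate
`pattern_seed` so train and test sessions generated with different noise
seeds share class definitions. Optional label noise reassigns a rounded
fraction of labels uniformly to a different class *after* generation, so a
noisy and a clean run with the same seed differ only in the flipped labels.

What the simulator does *not* emulate — and therefore what passing tests do
not establish about real recordings: volume conduction and realistic
spatial mixing, EOG/EMG artifacts, non-stationary drift across a session,
subject-to-subject variability, and the narrow-band but non-sinusoidal
shape of real mu rhythm. Results on the benchmark validate the machinery
(losses, gradients, optimization, the direction of the regularization
effects), not competition-level accuracy.

## Study conditions used by the automated checks

The acceptance script and the heavier tests run three experiments whose
conditions are fixed as follows (sizes chosen to make the phenomena visible
at desk scale on one CPU):

* **Separable recovery** — 2 classes, 8 channels, 500 samples,
  `rho = 0.8`, 100 training and 50 test trials per class (data seeds 7/8),
  60 epochs, batch 32, `P1 = 5`, `P2 = 10`. The model should essentially
  solve this (≥ 90% test accuracy); the same pipeline at `rho = 0` must
  stay within the 95% binomial band of chance.
* **Discriminative effect** — on the separable setup, training with
  \(\alpha_{ct} = 0.5\) versus \(\alpha_{ct} = 0\)
  (\(\alpha_{lsr} = 0.5\) both) across three training seeds; the center
  loss should strictly reduce the intra-class variance of the test-set
  features in at least two of three seeds. Dispersion is computed on the
  raw penultimate features, never on the 2-D PCA projection (projection
  discards variance and would bias the comparison; PCA is display only).
* **Generalization effect** — label smoothing's benefit shows where
  overfitting actually occurs: small, noisy training sets, the regime that
  motivates the method in the first place. Conditions: 30 training trials
  per class with 10% label noise, weaker ERD (`rho = 0.4`, the
  "hard-subject" regime where the original overfitting curves were
  observed), 100 epochs, \(\alpha_{lsr} = 0.5\) versus \(0\) with
  \(\alpha_{ct} = 0\). The comparison metric is the final standard test
  cross-entropy, which is comparable across objectives; smoothing should
  win in at least two of three seeds. At the easy 100-trials-per-class,
  `rho = 0.8` setting the unregularized model never enters the overfitting
  regime within 60 epochs and the contrast does not appear — that negative
  result is expected and documented rather than hidden.

## Worked example

```{r example}
library(micnn)

train_set <- generate_dataset(sim_config(
  n_classes = 2, trials_per_class = 100, n_channels = 8, n_samples = 500,
  rho = 0.8, seed = 7))
test_set <- generate_dataset(sim_config(
  n_classes = 2, trials_per_class = 50, n_channels = 8, n_samples = 500,
  rho = 0.8, seed = 8))

cfg <- model_config(T = 500, E = 8, M = 2, P1 = 5, P2 = 10)
fit <- train_model(train_set, test_set, cfg,
                   train_config(batch_size = 32, epochs = 60, seed = 7))
glance(fit)
autoplot(fit)

feats <- extract_features(fit$model, test_set)
class_dispersion(feats, test_set$labels)
plot_features(feats, test_set$labels)

run_ablation(train_set, test_set, cfg,
             train_config(batch_size = 32, epochs = 60, seed = 7),
             "alpha_ct", c(0, 0.5))
```

## Known limitations

* No GDF reader is included: competition recordings must be epoched
  externally (or via `epoch_trials()` once the continuous signals and event
  tables are in R), then stored with `save_trialset()`. The conventional
  splits (first session train / second test for the 4-class set; sessions
  1–3 train / 4–5 test for the 2-class set) are then a matter of which
  archives you build.
* The engine is CPU-only and single-threaded beyond BLAS; it is sized for
  desk-scale experiments (hundreds of trials, tens to hundreds of epochs),
  not for GPU-scale replication of full benchmark tables.
* Benchmark-scale numbers (e.g. mean accuracies near 80% on the 4-class
  competition dataset) require the real recordings and 750-epoch training
  per subject; nothing in this package's tests claims them.
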