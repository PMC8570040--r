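# micnn

Generalizable and discriminative training for motor-imagery EEG decoding.

## What this solves, and for whom

Subject-dependent motor-imagery (MI) brain–computer interfaces must decode
which movement a user *imagines* from a few hundred noisy EEG trials. Under
those conditions a CNN trained with the plain cross-entropy tends to fail in
two characteristic ways: it grows **overconfident** (and memorizes corrupted
or noisy trials — poor generalization), and its penultimate features are
merely **separable**, not discriminative (classes straddle the decision
boundary correctly but spread widely). `micnn` is for BCI/neuroinformatics
researchers who want a compact, fully reproducible R implementation of a
training scheme that fixes both by changing the *objective*, not the
architecture.

## The method

A compact temporal → depthwise-spatial → separable CNN (EEGNet family;
`F1 = 8` temporal filters of kernel `K1 = 32`, depth multiplier `D = 2`,
`F2 = 16` separable filters, average pooling `P1 = P2 = 8`, batch norm and
ELU throughout) is trained by minimizing

```
L = L_cl + α_lsr · L_lsr + α_ct · L_ct
```

- `L_cl = −Σ_i log q_θ(y_i | x_i)` — softmax cross-entropy;
- `L_lsr = Σ_i H_i(u, q_θ)` — **label-smoothing regularizer**, the
  cross-entropy against the uniform distribution `u = 1/M`; equivalent to
  training on smoothed targets `(1−ε)·onehot + ε·u` with
  `ε = α_lsr/(1+α_lsr)`; penalizes overconfidence;
- `L_ct = ½ Σ_i ‖x_i − c_{y_i}‖²` — **center loss** on the flatten-layer
  features, with per-class centers `c_j` updated by a damped running-mean
  rule; shrinks intra-class variance.

Defaults: Adam at 0.001, batch 64, `α_lsr = α_ct = 0.5`. The
forward/backward engine is hand-written in RcppArmadillo (gradients verified
against finite differences in the test suite) and is fully deterministic
under a seed. A synthetic MI session generator — band-limited mu/beta
rhythms over 1/f noise, with class identity expressed as event-related
desynchronization on class-specific channel subsets — makes the entire
pipeline testable without any data download.

## Worked example

```r
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
#> # A tibble: 1 × 8
#>   epochs train_accuracy test_accuracy train_loss test_loss test_cross_entropy
#>    <int>          <dbl>         <dbl>      <dbl>     <dbl>              <dbl>
#> 1     60              1             1      0.789     0.851              0.184

feats <- extract_features(fit$model, test_set)
class_dispersion(feats, test_set$labels)
#> <dispersion_summary> 2 classes | intra-class variance 0.5256 | inter-center distance 1.761

run_ablation(train_set, test_set, cfg,
             train_config(batch_size = 32, epochs = 60, seed = 7),
             "alpha_ct", c(0, 0.5))
#>   parameter value test_accuracy test_cross_entropy train_accuracy
#> 1  alpha_ct   0.0             1          0.2021821              1
#> 2  alpha_ct   0.5             1          0.1840317              1
```

Reading: the network solves the separable synthetic task outright (100%
test accuracy; at `rho = 0` the identical pipeline sits at chance), and
turning the center loss on tightens the test-feature clusters — repeating
the ablation across seeds shows roughly an order of magnitude less
intra-class variance with `α_ct = 0.5` than without. `autoplot(fit)` draws
the learning curves and `plot_features(feats, labels)` the 2-D PCA feature
map.

A command-line front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "micnn.R", package = "micnn"))') \
  simulate --config cfg.yaml --out session.rds
# likewise: train, ablate, evaluate
```

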