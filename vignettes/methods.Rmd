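---
title: "Methods: GAN-based augmentation for imbalanced CTG classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GAN-based augmentation for imbalanced CTG classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(ctgaug)
```

This vignette documents the model, the numerical choices behind the
implementation, and the limitations we observed. All code chunks are
illustrative (`eval = FALSE`); the README shows a runnable end-to-end example
with its output.

## The problem and the pipeline

Cardiotocography screening data is severely imbalanced: in the default
fixture configuration, normal records outnumber pathological ones 56:1 in the
training partition. A classifier minimizing average loss on such data can
spend almost all of its gradient signal on the majority class and still score
high accuracy. The pipeline counters this by synthesizing minority-class
records with one generative model per class, then learning a shared
representation on the expanded data:

1. encode each record as a 14-column numeric feature row (four CTG summary
   features with deceleration one-hot encoded, plus five clinical features);
2. train one BEGAN per minority class on that class's real training rows;
3. draw synthetic rows per an augmentation plan and append them to the real
   training rows (the *expanded dataset*);
4. train an autoencoder on the expanded dataset and freeze its encoder;
5. train a small classification head on the encoder codes;
6. evaluate on the real, untouched test partition.

Step 6 is a hard boundary: synthetic rows exist only on the training side.
Every result object carries a hash of the test partition, and the comparison
tools refuse to compare models evaluated on different partitions.

## BEGAN: model and parameters

The discriminator $D$ is itself an autoencoder over feature rows; its loss on
a batch is the mean absolute reconstruction error $\mathcal{L}(\cdot)$. With
generator $G$ and latent draws $z \sim U(-1, 1)^{n_z}$, training balances

$$\mathcal{L}_D = \mathcal{L}(x) - k_t \, \mathcal{L}(G(z)), \qquad
  \mathcal{L}_G = \mathcal{L}(G(z)),$$

where the control variable $k_t$ follows a proportional controller
$k_{t+1} = \mathrm{clamp}_{[0,1]}(k_t + \lambda\,(\alpha \mathcal{L}(x) -
\mathcal{L}(G(z))))$ with $k_0 = 0$, gain $\lambda = 10^{-3}$ and diversity
ratio $\alpha = 0.5$. Convergence is tracked by

$$M = \mathcal{L}(x) + |\alpha \mathcal{L}(x) - \mathcal{L}(G(z))|,$$

and training stops the first epoch $M$ falls below 0.058, or at the epoch cap
of 280. Both networks are dense: the generator maps
$n_z = 50 \to 80 \to d$ and the discriminator $d \to 80 \to b \to 80 \to d$.
All of these values are `began_config()` parameters.

### Why the discriminator has a narrow bottleneck

The equilibrium mechanism assumes the discriminator reconstructs real rows
better than generated ones. If the code width $b$ is at least the feature
dimension $d$, a dense autoencoder can learn the identity map: it then
reconstructs *everything* perfectly, $\mathcal{L}(x) \to 0$ while
$\mathcal{L}(G(z))$ plateaus, $k$ never engages, and the generator collapses
to a point. We observed exactly this failure with a wide code (real loss
0.011, fake loss 14 times higher, $k \approx 0$ throughout). The default is
therefore $b = \min(n_z, \max(1, \lfloor d/2 \rfloor))$, overridable via
`began_config(bottleneck_dim = ...)`. Per-epoch diagnostics
(`model$diagnostics`: $M$, both losses, $k$) make this failure mode visible.

### Why the bottleneck (and the autoencoder code layer) is linear

Hidden layers use rectifiers, but a *narrow* rectified code is fragile: if
all of its pre-activations go negative the code dies wholesale, gradients
through it vanish, and training freezes permanently. We observed a
one-unit-code autoencoder stuck at its initial reconstruction error for 1,000
epochs, and a discriminator whose real-data loss pinned at 0.41 on a
trivially reconstructable two-feature cloud. Both code layers are therefore
linear — the standard autoencoder design, which loses no capacity because the
adjacent layers stay nonlinear. After the change the one-unit autoencoder
reaches a reconstruction error below 0.1% of its initial value on a linear
manifold.

### Internal standardization

Feature columns mix units (beats per minute, counts, 0/1 indicators,
temperature). Both the BEGAN and the autoencoder standardize their input
per-feature internally; the scaler is stored on the model, inverted when
synthetic rows are generated, and applied inside `encode()` and
`reconstruction_error()`, so users only ever see data units. Without this,
the mean-absolute-error objective is dominated by the widest columns, and the
one-hot deceleration indicators — which carry most of the label signal —
are effectively ignored by the generator (we measured suspicious-class recall
dropping from 0.48 to 0.06 without it).

## Augmentation plans

`make_plan()` implements two policies. Binary: every class is topped up with
6,000 synthetic rows. Multiclass: any class holding less than 10% of the
training data receives 10,000 synthetic rows; majority classes receive none.
Both counts are parameters. The expanded dataset size is exactly the real
training size plus the plan total, and every row carries a
`real`/`synthetic` provenance tag.

## Classifier heads

Three heads operate on either raw features or encoder codes:

- `dnn`: dense 32 → 16 → classes;
- `cnn1d`: 32 convolution filters (kernel 3) over the input treated as a
  1-D sequence, then dense 16 → classes;
- `lstm`: two stacked LSTM layers of 64 units, then dense 32 → classes.

Model tags combine family and head: `cnn` (naive raw-feature CNN), `cnn_ae`
(encoder trained on real data only), `g_cnn_ae` (encoder trained on the
GAN-expanded data), and likewise for `dnn`/`lstm`. The encoder is frozen
during head training — byte-identical before and after, which the test suite
asserts by serialization.

## Evaluation

Per-class precision, recall and F1 come from the one-vs-rest confusion
counts; undefined ratios (zero denominators) are reported as `NA` with a
warning, never silently as 0. Repeated runs are summarized by mean, sample
standard deviation and a normal-approximation confidence interval. Two
classifiers on the same test partition are compared with an exact two-sided
McNemar test on the discordant pairs, $p = \min(1,\; 2\,P(X \le \min(b,c)))$
for $X \sim \mathrm{Bin}(b + c, 1/2)$, and with a percentile bootstrap CI of
the accuracy difference over paired row resampling.

## Problem sizes

The default fixture (29,400 train / 12,600 test, minority shares 3.3% and
1.7%) is this package's own choice of a realistic screening-scale shape; all
counts are `fixture_config()` parameters. Tests and the acceptance script use
a 10x-scaled-down version (4,200 records with the same shares) so the full
pipeline runs in seconds per model on one CPU.

## Design decisions

- **Plain-matrix networks.** The dense, convolutional and LSTM layers, Adam,
  and backpropagation are written in base R matrix code. This keeps the
  package dependency-free (`stats`, `utils`, `jsonlite`, `yaml`) and every
  computation deterministic given R's RNG state.
- **S3 throughout.** The objects are small tagged lists (configs, models,
  reports) with `print` methods; the data is tabular, so no formal class
  system is needed.
- **Seed fan-out.** One global seed is deterministically expanded into
  per-stage seeds (`derive_seed(global, stage_name)`), so stages are
  reproducible in isolation and pipelines are reproducible end to end; the
  CLI's `run-all` writes byte-identical metrics for identical seeds.
- **Deterministic fixture labels.** The labeling rule (count non-reassuring
  CTG features: 0 → normal, 1 → suspicious, ≥2 → pathological) partitions
  the 16 reassuring/non-reassuring patterns into 1/4/11, which fixes the
  relative richness of the three classes and makes every generated record's
  label recomputable.

## Limitations

- **Mode collapse on tiny classes.** On a 50-row pathological class spanning
  11 discrete feature patterns, the BEGAN concentrates mass near the class
  mean: synthetic means match the real means within 0.05 standard deviations,
  but the synthetic spread is roughly a fifth of the real spread. The
  augmentation still improves minority recall — mostly by upweighting the
  minority gradient — but the synthetic rows under-represent the class's
  diversity.
- **The benefit is regime-dependent.** The fixture's labels are a noise-free
  deterministic rule, so given enough classifier epochs the naive raw-feature
  model eventually solves the task and the augmentation margin disappears.
  The imbalance pathology — and the augmentation benefit — shows in the
  few-epoch regime, which is what the scaled experiment measures. On noisy
  real-world data the crossover would come much later, if at all.
- **Small test partitions are noisy.** With 11 pathological test rows, one
  row is a 9-point recall swing; the repeated-run standard deviations in the
  reports should be read accordingly.
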