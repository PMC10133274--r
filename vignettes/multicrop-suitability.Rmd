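---
title: "Weakly supervised multi-crop suitability mapping: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised multi-crop suitability mapping: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropsuit)
```

## The estimation problem

Agricultural yield statistics are published as *district-level means*: one
number per crop, district and year, covering thousands of heterogeneous
pixels. Land-suitability mapping wants the opposite — a per-pixel, per-crop
estimate of attainable yield (bushels/acre), including on land where the
crop is not currently grown. `cropsuit` implements a weakly supervised
estimator for this downscaling problem.

The training unit is an *aggregated example*: the group of pixels that
share a crop $c$, district $d$ and year $t$, together with the single
published yield $y_{c,d,t}$. The identifying assumption is that the
published district yield equals the mean of the (unobserved) pixel yields
over the crop's cultivated pixels in that district.

## Model

A multilayer perceptron maps the $F = 16$ soil–climate–landscape
covariates of one pixel to $C$ per-crop yield predictions
$\hat y_i \in \mathbb{R}^C$. The default architecture is
$16 \to 256 \to 512 \to 256 \to C$ with rectified-linear hidden units and
dropout on every hidden layer.

Supervision never reaches a single pixel. Instead an **averaging head**
aggregates the pixel predictions of a group,

$$\hat y_{c,d,t} = \frac{1}{n_{c,d,t}} \sum_{i=1}^{n_{c,d,t}} \hat y_{i,c},$$

and the loss compares this aggregate to the published district yield. Only
one crop is observed per group (a field grows a single crop per season), so
a one-hot **crop indicator** masks the per-crop absolute errors:

$$\mathrm{Loss} = I_{\mathrm{observed}}^{\top} E, \qquad
  E_c = \left| \hat y_{c,d,t} - y_{c,d,t} \right|.$$

The masked L1 loss has two structural consequences that the test suite
asserts numerically: (i) each example contributes gradient only to the
observed crop's output head, while the shared layers receive gradient from
every example — this is how the model pools information across crops; and
(ii) perturbing the (nonexistent) labels of unobserved crops cannot change
the loss, bit for bit.

Covariates and labels are standardized to zero mean and unit variance
before training; predictions are inverse-transformed back to bushels/acre.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `hidden_dims` | 256, 512, 256 | hidden-layer widths |
| `dropout_rate` | 0.95 | probability a hidden unit is **dropped** during training |
| `learning_rate` | 1e-3 | Adam step size |
| `lr_decay` | 0.02 | inverse-time step decay per epoch |
| `epochs` | 300 | passes over the examples |
| `batch_groups` | 8 | aggregated examples per optimizer step |
| `weight_by_pixels` | off | weight a batch's examples by pixel count |

Two readings of "95% dropout" are possible; we take it as the
*drop*-probability and expose it as configuration. At inference dropout is
off (inverted scaling during training), so prediction is deterministic.
Heavy dropout is a sensible regularizer for the real, small,
weakly-labelled data the method targets, but it destroys signal in small
controlled experiments; recovery tests therefore run with
`dropout_rate = 0`.

The L1 objective has a constant-magnitude subgradient near its optimum, so
Adam with a fixed step oscillates at the step-size scale instead of
settling; the inverse-time decay (`lr_decay`) shrinks late steps. The
training log records the mean masked loss per epoch; because of the
residual oscillation, convergence statements are about the level the loss
*reaches* during training, not the final epoch alone.

Batch loss is the unweighted mean of per-example masked losses; weighting
by group pixel count is available (`weight_by_pixels`) but not the
default, since the label of a large district is not more trustworthy per
se. Weight initialisation is variance-scaled symmetric Gaussian keyed to
the seed; all randomness (initialisation, shuffling, dropout) flows from
`model_config(seed = )`, making training bit-reproducible.

## The synthetic generator

The package bundles a generator whose output has the statistical structure
the method assumes, with known ground truth:

* **Covariates** — white noise smoothed by an isotropic Gaussian kernel
  (`correlation_length`, pixels) and rescaled to mean 0, sd 1: spatially
  autocorrelated fields standing in for terrain, soil and climate layers.
* **Districts** — a nearest-seed (Voronoi) partition of the lattice:
  contiguous reporting districts of irregular size.
* **True response** — per crop, a smooth function
  $y_c(x) = \max\{0,\ \beta_{0c} + g\, x^\top w_c + \kappa g\,((x^\top v_c)^2 - 1)\}$
  with offsets drawn from 50–70 bushels/acre and gain $g = 10$; the
  curvature term ($\kappa$, default 0) adds a non-monotone direction. Crop
  weight vectors share a common component controlled by
  `cross_crop_correlation` $\in [0,1]$ — at 1 all crops respond
  identically up to offsets; at 0 they are independent. The clamp at 0
  keeps yields physical and is essentially inactive at the default
  offset/gain.
* **Crop placement** — a chosen fraction of pixels is cultivated; each
  cultivated pixel receives one crop sampled with probability
  $\mathrm{softmax}(s \cdot y_c(x))$. Sharpness $s = 0$ gives uniform
  placement; large $s$ plants each pixel's best crop. This reproduces the
  central observational confound: crops are observed preferentially where
  they grow well.
* **Labels** — per (crop, district, year) group, the mean of the true
  pixel yields plus Gaussian noise (`label_noise_sd`), truncated at 0.

What the generator does *not* emulate: real covariate marginals and
cross-correlations (all features are Gaussian and independent of each
other), temporal persistence of weather across years (each year's grid is
drawn fresh), measurement structure of the source rasters, and district
boundary changes between reporting periods (supported but off by default).
Passing recovery tests therefore show the estimator does what it claims
under its own assumptions — not that those assumptions hold for any real
landscape.

Within-district yield heterogeneity and label noise levels are not
published quantities; the defaults (noise 0–2 bushels/acre in the bundled
experiments, response smoothness as above) were chosen once as plausible
desk-scale values and are not calibrated to any real region.

## Evaluation protocol

Cross-validation splits by **district**, never by record: all examples of
a held-out district leave the training set together, so validation
measures generalisation to unseen regions rather than interpolation. The
plan draws `districts_per_fold` districts per fold without replacement and
without reuse across folds until the eligible pool is exhausted, then the
pool resets; this accommodates more draws than districts, as happens when
several periods or repetitions are evaluated over a fixed district set. A
crop with no validation record in a fold is excluded from that fold's
statistics and its `n_val_sets` count reflects it.

The standardizer is fitted on each fold's training examples only;
`global_standardize = TRUE` reproduces the alternative of standardizing
once before splitting, which is faster but leaks validation statistics.
The leakage-free variant is the default.

Reported metrics follow the conventional table shape: per-crop MAE mean
and sample SD across folds, the count of evaluable folds, and the relative
error — MAE as a percentage of the crop's observed yield range (max − min
over all labels), computed from the data rather than configured. The
single-crop baseline trains one single-output network per crop on that
crop's records alone, with the same architecture and budget, and the
fold-reduction factor is the per-crop ratio of single-crop to multi-crop
MAE.

## Mapping

`predict_suitability()` predicts every pixel for every year and averages
the years pixelwise (unweighted). A pixel that is nodata in any year is
nodata in the average — propagation is deliberate, so a map value always
summarises the same number of years. External validity masks (e.g. a
vegetation-index threshold) turn excluded pixels to nodata and never touch
the rest. Zonal summaries average non-nodata pixels per zone and omit
empty zones. On export, negative predicted yields are clamped to 0
(unsuitable land is "yield 0"); in-memory maps keep the sign for
diagnostics.

Raster export uses 32-bit-float TIFF with values affinely rescaled to the
unit interval and the offset/scale, nodata sentinel (−9999), band names
and pixel footprint stored in a JSON sidecar; round-trip fidelity is at
float32-quantization level. The files carry no georeferencing tags — the
lattice is the coordinate system, with row-major, 0-based indexing in all
exported tables.

## Problem sizes in the bundled experiments

The test suite and the acceptance script run entirely on generated data at
desk scale, chosen to finish in minutes on one CPU:

* recovery: 32 × 32 lattice, 6 crops, 32 districts, 8 years, linear truth,
  zero label noise, neutral placement, dropout 0, single 32-unit hidden
  layer — held-out-pixel $R^2$ against the true response is the headline
  number;
* multi- vs single-crop: 24 × 24 lattice, 9 crops, 10 districts, 2 years
  (≤ 20 labels per crop), cross-crop correlation 0.9, curvature 0.7,
  label noise 2, a half-width 128-256-128 stack with dropout 0.95 —
  conditions where each crop alone is label-starved but the crops share
  response structure, which is the regime the multi-crop design targets.
  The comparison is directional (does pooling help most crops?) and run
  over several seeds; with cross-crop correlation 0 the advantage is not
  expected and not asserted.

## Known limitations

* No spatial or temporal covariance modelling: pixels are conditionally
  independent given covariates, by design.
* The averaging head identifies pixel-level structure only up to functions
  whose group means match the labels; with few, large groups the pixel
  field is underdetermined, and recovery degrades gracefully rather than
  failing loudly.
* District labels are treated as exact means; systematic reporting bias is
  indistinguishable from response offsets.
* Raster I/O is lattice-based; reprojection, resampling and georeferenced
  export belong to a GIS layer outside this package.
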