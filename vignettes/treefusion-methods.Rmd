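---
title: "Multi-sensor fusion for crown-level taxon classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-sensor fusion for crown-level taxon classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treefusion)
```

## The problem

Airborne campaigns over forested sites deliver three complementary data
products per plot: decimeter-resolution RGB orthoimagery (crown texture and
color), meter-resolution imaging-spectrometer reflectance (hundreds of
narrow bands carrying chemical/structural signatures), and discrete-return
lidar point clouds (vertical canopy structure). Given rectangular crown
bounding boxes joined to field records with taxon labels, the task is to
predict the species or genus of each crown — including, at deployment,
crowns of taxa never seen during training, which must be diverted to an
"Other" class rather than silently mislabeled.

`treefusion` implements a two-stage approach: a convolutional network turns
each crown's RGB chip into taxon probabilities, and a shallow fusion
multilayer perceptron learns to combine those probabilities with the crown's
centroid reflectance spectrum and a lidar pseudo-waveform.

## Per-crown feature construction

**Coordinate conventions.** Rasters are indexed row-major from the
north-west corner; a cell contains the points `[lo, hi)` of its extent along
both axes (measuring y as distance south of the top edge), so a centroid
lying exactly on a cell edge belongs to the cell with the larger index.
Point-in-crown tests use the same half-open convention. Crowns are required
to fall within a single plot tile.

**RGB chips.** Clipping a tile to a crown box keeps exactly the cells whose
centers fall inside the box. Chips are standardized by resizing the short
side to 224 px (bilinear, via EBImage; upsampling is allowed, so degenerate
slivers such as a 1 × 6-pixel crown are valid), center-cropping the long
side, and normalizing channels with the conventional ImageNet means and
standard deviations (configurable — the recipe, not the constants, is the
contract). The crop/resize order and interpolation are deliberate,
documented choices; any deterministic recipe producing a fixed square would
serve.

**Reflectance.** The spectrometer grid is `380 + 5k` nm for `k = 0…425`;
the nominal upper end of the range is treated as approximate since the band
count (426) is what downstream dimensions depend on. The crown's feature is
the band vector of the single cell containing the polygon centroid, divided
by the storage scale factor (10000 by the usual convention for reflectance
integers). Two water-vapor windows, 1340–1445 nm and 1790–1960 nm inclusive,
remove 22 + 35 = 57 bands, leaving 369. The windows are configurable; the
defaults were chosen as standard water-absorption regions sized so that the
default grid yields exactly 369 good bands, and a different count under a
changed configuration is surfaced as an error at assembly time, not hidden.

**Lidar pseudo-waveform.** Heights below the 1st or above the 99th
percentile of the whole point-cloud file (linear interpolation between order
statistics, bounds inclusive) are discarded as anomalies — below-ground
returns from timing errors, spuriously high returns from e.g. birds. The
filter runs per file, before crown clipping, because the percentiles are
statistics of the full cloud. Clipped points fall into `n_bins = 39`
equal-width bins spanning 0–40 m (width 40/39 ≈ 1.026 m): the bin count is
the binding constant because it fixes the 40-element lidar block and hence
the 440-element fusion vector, while "one-meter bins over 0–40 m" cannot
simultaneously hold with 39 bins. Edges are half-open with the final bin
closed; points above 40 m after filtering are clamped into the top bin and
points below 0 m into the bottom bin (with a message), so no clipped point
is silently lost; an empty crown yields the all-zero waveform rather than an
error, keeping the pipeline total on sparse scenes. The feature block is the
39 proportions followed by the total point count.

## The fusion network and the soft F1 loss

The fused vector is the fixed-order concatenation (RGB probabilities,
good-band reflectance, lidar block): `31 + 369 + 40 = 440` elements in the
reference configuration. The network has hidden layers of 64 and 32
rectifier units and a softmax output over the training taxa; training is
plain momentum-free minibatch SGD (batch 64) under a one-cycle schedule
peaking at `1e-2` for 20 epochs, all configurable. The one-cycle shape is a
linear warm-up over the first 25% of steps, then cosine decay; the policy
name fixes only the single-peak shape, the fractions are our choice.

The objective is the per-example soft F1 loss

$$L(\theta) = \frac{1}{K}\sum_{k=1}^{K}\left[1 -
\frac{2\theta_k y_k}{2\theta_k y_k + \theta_k(1-y_k) + (1-\theta_k)y_k +
\varepsilon}\right],$$

with `ε = 1e-7` guarding the denominator, averaged over the examples of a
minibatch. For one-hot `y` with true class `t` this reduces to
`1 − 2θ_t/(K(1 + θ_t + ε))`: the loss depends on `θ` only through the true
class probability, is strictly decreasing in it, equals 1 exactly at
`θ_t = 0`, and approaches `(K−1)/K` as `θ_t → 1` (so a perfect 2-class
prediction scores ≈ 0.5, not 0). Because every class term enters the
average, a confident wrong prediction on a rare class costs as much as on a
common one — the imbalance-robustness motivation for preferring it over
cross-entropy, which remains available as a configuration switch. `θ` is
the post-softmax output, as required by the `[0, 1]` domain of the loss.

Feature columns are z-scored with training-set statistics stored in the
model: the lidar total-point count is two orders of magnitude larger than
the probability and reflectance entries, and unscaled it dominates the
early optimization.

```{r soft-f1}
soft_f1_loss(c(1, 0), c(1, 0))        # perfect 2-class prediction
soft_f1_loss(c(0, 0.4, 0.6), c(1, 0, 0))  # no mass on the truth
```

**Open-set rule.** If the maximum fused probability is below 0.5, the
augmented vector receives `Other = 0.5` and the original entries are
rescaled by 0.5; otherwise the vector passes through with `Other = 0`
(a maximum of exactly 0.5 counts as confident — the rule fires on "less
than"). Both the threshold and the assigned mass are configuration values;
0.5 has no reproducible derivation beyond inspection of probability
histograms, so it is a parameter, not a constant. Hard labels are the
argmax of the augmented vector, ties broken toward the lowest class index.

```{r other-rule}
apply_other_threshold(c(0.4, 0.3, 0.3))
```

## The RGB backbone

No pretrained weights ship with the package, so the backbone family is a
randomly initialized stack of 3 × 3 convolution blocks (rectifier + 2 × 2
average pooling) with a global-average-pooled softmax head, trained with
cross-entropy. The named depths 18/34/50/101/152 map to progressively
deeper stacks (2–6 blocks) so the backbone-comparison harness — one model
per depth, tabulate validation macro F1/precision/recall, select the
argmax with ties broken toward the smaller depth — exercises the selection
procedure end to end; `"small"` (one block) is the default. To keep the
arithmetic tractable in interpreted code the standardized chip is
average-pooled by a factor of 8 (224 → 28) before the first convolution;
this preserves the color and coarse-texture cues the synthetic scenes carry.
Published depth-comparison numbers obtained with ImageNet-pretrained
residual networks on real imagery are not reproducible under this setup and
are not a target of the test suite.

## The synthetic scene generator

The generator exists so that every downstream stage has known ground truth.
Each taxon archetype carries a mean 426-band spectrum (a vegetation-like
baseline — green bump, red edge, NIR plateau, SWIR decay — plus smooth
random perturbations, quantized to 1e-4 so scaled-integer storage
round-trips exactly), a crown color, a crown side-length range (1.5–5.5 m)
and a Gaussian canopy-height profile (means 6–32 m, spreads 0.5–2.5 m).
Archetypes are resampled until all pairs differ by more than 0.05 in at
least one band, by more than 0.1 in color distance and by more than 0.5 m
in mean height, so classes are separable by construction; additive Gaussian
sensor noise (defaults: 0.02 on colors, 0.01 on reflectance) makes them
separable-but-noisy. Setting both noise levels to zero makes the
centroid-spectrum identity exact, which is what the end-to-end recovery
test exploits.

Plots follow the reference product geometry: 20 m sides, 0.10 m RGB cells,
1 m spectrometer cells, and a Poisson point count at 3.15 returns/m² with
crown points drawn from the taxon height profile and background points near
the ground. Crowns are non-overlapping rectangles placed by rejection
sampling (4–8 attempts per plot by default); overlap handling in real data
is out of scope. Below-ground and above-canopy anomalies (2 + 1 per plot by
default) are injected so the percentile filter has real work to do. Default
class weights decay geometrically with ratio 0.72, putting roughly 28% of
crowns in the dominant class for 31 taxa — the same order of skew as real
crown censuses with one dominant species. Scenes are written as plain
formats: TIFF + JSON sidecar for RGB, CSV + sidecar for the cube, XYZ text
for points, GeoJSON for crowns, CSV for field records; test-set labels go
to a separate withheld file, mimicking a competition release.

What the generator does *not* emulate: radiative-transfer effects, shadows
and image distortion, spatially correlated texture inside crowns,
crown-boundary mixing, sensor noise physics, or taxa whose signatures
overlap. Passing the recovery tests therefore shows the pipeline's
plumbing, optimization and post-processing are correct — not that the
method attains any particular accuracy on real imagery, where those effects
dominate the error budget.

## Problem sizes and the training schedule

The shipped studies run on scaled-down scenes chosen to exercise every code
path at desk scale: 5 uniformly weighted taxa, 12 training plots and 2–4
test plots (roughly 60–80 crowns), RGB at 12 epochs. At these sizes the
reference fusion schedule (20 epochs × batch 64) amounts to ~20 SGD steps —
an order of magnitude fewer optimization steps than the ~260 the same
schedule yields at the reference data size — so the desk-scale studies
rescale the budget to 60–150 epochs with a one-cycle peak of 5e-2,
restoring a comparable step count. Package defaults remain the reference
values; the rescaled schedule is passed explicitly where used.

Two recovery properties anchor the test suite: on a noisy scene the fusion
network reaches at least 0.9 holdout accuracy (it attains 1.0), and on a
zero-noise scene the full pipeline — RGB training included — recovers every
withheld test crown exactly, because the fused features of each taxon are
then identical across crowns up to lidar sampling variation.

## Numerical choices and degenerate inputs

* Percentiles: type-7 linear interpolation; filter bounds inclusive.
* Softmax logits are max-shifted before exponentiation.
* `f1_from_pr`, precision and recall return 0 on zero denominators;
  zero-support classes stay in reports and macro averages.
* Cross-entropy clips probabilities below at `1e-15` (configurable); a true
  class entirely absent from the probability columns contributes the
  clipped value, so reports on open-set submissions remain finite.
* Non-rectangular crown polygons collapse to their bounding box with a
  warning; unlabeled crowns are retained (evaluation mode), not dropped.
* Determinism: every stochastic step (archetypes, placement, noise, splits,
  initialization, shuffling) flows from explicit seeds derived from one
  global seed; runs are single-threaded, so fixed seeds give bit-identical
  scenes, models and metrics.
* Stage caching: `run_synthesize` records md5 digests of its configuration
  and outputs and skips regeneration when nothing changed.

## Known limitations

The backbone is far smaller than the residual networks used on real
imagery, and no pretrained weights are involved; RGB-stage accuracy on
synthetic scenes is accordingly modest (the fusion stage, which sees the
reflectance block, carries the recovery results). LAS/LAZ binary point
clouds and ESRI shapefiles are not read — XYZ text and GeoJSON are the
supported carriers. Batch-level soft F1 (computing the F1 surrogate over a
whole minibatch rather than averaging per-example losses), K-fold
calibration of the "Other" threshold, texture features and spectral
dimensionality reduction are out of scope.
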