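---
title: "Detecting and grading greenhouse strawberries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and grading greenhouse strawberries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strawdetect)
```

## The problem

Counting and grading strawberries in a greenhouse from near-ground RGB
imagery supports both harvest planning and variety selection. Two image
properties make this harder than generic object detection: fruit are small
and numerous (a full bed image holds on the order of 100–150 fruit), and
they are frequently occluded by leaves or adhered to neighbouring fruit, so
a detector's missed fruit are not random — they are concentrated exactly
where the agronomically interesting clusters are.

`strawdetect` implements a complete desk-scale pipeline for this problem:

1. a seeded synthetic-scene generator with exact ground truth,
2. VOC-dialect XML annotation IO,
3. the photometric augmentation / patching / splitting stack,
4. a trainable two-stage detector built from residual convolution blocks,
5. curvature-guided watershed post-processing for occlusion and adhesion,
6. bounding-box plumpness grading, and
7. evaluation indices with robustness-experiment harnesses.

Everything is deterministic given a seed: scenes, augmentation, training,
and experiments are pure functions of their configuration.

## The synthetic scene generator

Real greenhouse bed imagery with expert box annotation is expensive and
rarely shared, so the package ships a generator whose scenes exercise every
downstream stage with known ground truth. A scene is a textured green-brown
bed with `n_fruit` superellipse fruit; each fruit's half-width is drawn
from `fruit_radius_range` and its height/width ratio from
`fruit_aspect_range` — the latter is what the grading module measures, so
every grade band is reachable by construction. A configurable fraction of
fruit is placed overlapping a neighbour (adhesion) and a fraction is
partially covered by a leaf-shaped occluder. Ground truth records the tight
box of each fruit's *pre-occlusion* rendered extent plus per-fruit
adhesion/occlusion flags, which is what lets tests distinguish "the
detector missed an exposed fruit" from "the fruit was genuinely hidden".

Illumination follows the five field clusters (1000–6000 Lx). The mapping
from lux to pixels is a linear luminance gain `0.5 + lux / 8000`, clipped
at channel saturation, so 4000 Lx is nominal exposure and brightness is
monotone in lux; sensor noise is additive Gaussian with a constant standard
deviation (`noise_sigma`, default 2 grey levels), i.e. a read-noise-limited
camera at fixed exposure. These were fixed once as renderer definitions.
Two consequences are worth stating plainly: a dark scene here is a
*contrast-compressed but still clean* image, and a bright scene brings the
red-tinged soil texture closer to fruit colour. Real low-light field images
additionally suffer shot noise and motion blur that this generator does not
model, so illumination-robustness results at desk scale describe this
renderer, not field photometry (see "What the tests do and do not show").

Default scene sizes: full scenes are 640 x 480 with 120 fruit of radius
8–16 px (matching the ~100–150 boxes per bed image of the motivating
set-up); the `tiny_scene_config()` preset used throughout the tests is
64 x 64 with 5 fruit of radius 4–7 px, which keeps CPU training in
minutes.

## Preprocessing

`median_denoise()` applies an exact windowed median (default 3 x 3) per
channel with reflection edge handling; the implementation sorts the window's
shifted copies with a vectorised compare-exchange network, so it is exact
(a constant image is a fixed point), unlike histogram-approximation median
filters.

`augment_image()` implements the nine photometric transforms used to
expand small fruit datasets: brightness, chroma and contrast enhanced to
1.2x, sharpness to 2x; the same four attenuated to 60%, 60%, 60% and 10%;
plus Gaussian noise of variance 0.01 on [0, 1] intensities (about 25.5
grey levels at 8 bit — the variance is interpreted on the normalised
scale, since grey-level variance 0.01 would be a no-op). With the original
included the expansion is exactly 10x: 400 originals become 4000 images,
and an 80/20 split yields 3200/800. Box annotations are copied verbatim:
all transforms are photometric.

One ordering question is genuinely open: whether to split into train/test
before or after augmentation. Splitting after (the count-faithful order)
lets augmented copies of one scene land on both sides of the split, which
leaks information. The pipeline defaults to splitting originals first and
augmenting each side (`cmd_preprocess(split_after_augment = FALSE)`), with
the count-faithful order available behind the flag. Similarly, whether
denoising precedes augmentation is unstated in common descriptions of this
stack; the pipeline denoises first, so the noise-augmentation image is
noise added to a clean image rather than to residual sensor noise.

`split_patches()` tiles large images into 256 x 256 patches on a
`ceil(H/ps) x ceil(W/ps)` grid with edge tiles taken flush with the border:
tiles may overlap near edges but contain only real pixels, and stitching
them back reproduces the image exactly. Boxes follow their patches when the
patch contains at least half the box's area (inclusive), clipped and
translated to tile coordinates.

## The detector

The detector is a two-stage region-proposal architecture over a residual
backbone, sized so that it trains from scratch on one CPU in minutes:

* **Backbone** — four stages (M1–M4), each a stride-s 3 x 3 convolution
  followed by a residual block `y = F(x, W1, W2) + Ws x` (two 3 x 3
  convolutions in series; the bottleneck 1 x 1 / 3 x 3 / 1 x 1 variant is
  also provided as a standalone block). The shortcut is the identity
  within a stage; channel/stride changes live in the stage's entry
  convolution. ReLU is the backbone activation.
* **Proposal branch** — a 3 x 3 hidden convolution then 1 x 1 heads for
  per-cell, per-anchor objectness and box deltas (the standard
  centre-offset / log-size parameterisation). Anchors are chosen to
  bracket the synthetic fruit sizes; the tiny preset uses a single 11 px
  square anchor at stride 4.
* **Region head** — pooled ROI features pass through exactly one wide
  fully connected layer (2048 neurons at full scale), dropout after it,
  then the three-layer adaptive head N1–N3 of 1000 / 256 / 7 neurons with
  the hybrid activation
  `f(x) = ln(e^x + 1) - ln 2` for `x >= 0`, `0.01 x` for `x < 0` —
  continuous at 0, monotone, asymptotically `x - ln 2`. The head width 7
  is kept for architectural fidelity even though a single-category task
  only needs 2; the tiny preset uses a 2-unit head and the width is
  configurable. One deliberate deviation: N3's class unit is read as a
  *raw* logit for sigmoid scoring rather than being squashed through the
  hybrid activation first — the activation maps all negatives into
  `[-0.02, 0)`, which would floor every proposal score near 0.495 and
  remove the gradient needed to learn rejection of background proposals.

Dropout behaves classically: active during training, removed at test time
with outputs multiplied by the retention probability so downstream
magnitudes are preserved; inference is therefore bit-deterministic.

### Training

The loss is soft-Dice on the dense objectness map against binary
object-vs-background cell targets (a cell is positive when its centre lies
inside a ground-truth box), plus smooth-L1 box regression at positive
cells, plus soft-Dice classification of sampled region proposals through
the adaptive head (proposals are pooled with a stop-gradient, in the
spirit of stage-wise two-stage detector training). The optimiser is SGD
with momentum 0.9; the learning rate is 0.001 for the first 3000
iterations and 0.0005 afterwards; dropout is 0.5; the reference schedule
is 200 epochs at batch size 64. In tiny mode the schedule boundary scales
proportionally (the first 60% of iterations at the base rate, matching
3000 of a planned 5000).

Two numerical choices matter and are deliberate:

* **Low-prior bias initialisation.** The objectness and head class logits
  start at bias −2 rather than 0. Soft-Dice has a gradient plateau at
  p = 0.5: the denominator (sum of predictions plus targets) is maximal
  and per-cell gradients are an order of magnitude too small to escape it
  within a short schedule. Starting at a low foreground prior keeps the
  denominator near the target mass from the first step. This is the same
  prior-initialisation practice used by focal-loss detectors.
* **Multi-task loss weights.** The three terms are combined as
  `w_obj * dice + w_box * smoothL1 + w_head * dice`. Weighting between
  classification and regression terms is a free calibration in two-stage
  detectors and is not dictated by the architecture; the tiny preset uses
  (50, 5, 5), chosen once so the terms' gradient magnitudes are comparable
  for a from-scratch CPU run. At the reference scale the weights default
  to (1, 1, 1).
* **Gradient clipping.** Each batch gradient's global norm is clipped (to
  10 in the tiny preset; disabled by default at reference scale). The
  up-weighted Dice term makes early updates large relative to the 0.001
  learning rate, and without clipping a fraction of initialisation seeds
  oscillate through the first schedule phase instead of converging;
  clipping removes that failure mode without changing the loss.

Training aborts with the epoch index if the loss becomes non-finite, and
the returned `strawberry_detector` carries a per-epoch `loss_trace`
(`epoch, loss, lr`) with `print`, `plot` and `predict` methods.

### Inference

`detect()` thresholds objectness at 0.3 to form proposals (capped at 100),
decodes boxes, scores each with the geometric mean of objectness and the
head's class probability, keeps scores at or above `score_threshold`
(default 0.5), and applies standard non-maximum suppression at IOU 0.5.

A seeded `oracle_detector()` (ground truth plus uniform jitter and random
drops) stands in for the trained model wherever a downstream stage should
be tested independently of training quality.

## Occlusion and adhesion post-processing

Detection output is refined by a shape pipeline that works on the image,
not the network:

1. **Binarize** — fruit pixels by red dominance
   (`R - max(G, B) > 0.10` and `R > 0.25`), cleaned by morphological
   open/close with a 3 x 3 element; connected components are labelled and
   their contours traced.
2. **Isolation test** — a component is isolated iff its solidity
   (area / convex-hull area) is at least 0.92 *and* its contour curvature
   profile has no outliers. Components under 20 px are indeterminate and
   treated as isolated. Curvature is estimated by finite differences over
   a 7-point arc-length window on the circularly smoothed contour; points
   with `|curvature − median| > 3 MAD` are outliers (the MAD is floored at
   0.001 1/px so flat-sided contours still flag their corners). The sign
   is normalised so convexity toward the region interior is positive. At
   a fruit–fruit junction or an occluder cut the curvature changes
   abruptly, which is exactly what the outlier test detects.
3. **Watershed separation** — for each non-isolated component the outlier
   contour pixels are deleted, the distance transform computed, and a
   seeded watershed run with regional maxima merged within 5 px. A
   component that fails to split stays single, so the label count never
   decreases, and no pixels are created.
4. **Box reconciliation** — a detection box overlapped (IOU ≥ 0.3) by two
   or more split labels is replaced by the labels' tight boxes; labels
   overlapping no box at all are added as new detections with score 0.5
   and a `recovered` flag. How watershed output re-enters the detection
   list is an open design point; this additive/replacement rule is the
   package's operational choice and is monotone in recall by
   construction.

The thresholds (solidity 0.92, MAD multiplier 3, window 7, merge radius
5 px, association IOU 0.3) are not physical constants; they were fixed
once against the synthetic fixtures and live in a single constants block.

## Plumpness grading

For globose varieties the bounding box is a minimal external rectangle and
the length-to-width ratio `(ymax − ymin) / (xmax − xmin)` is a plumpness
proxy with ideal value 1. Ratios above 1 (portrait boxes) are folded by
reciprocal so the measure is rotation-symmetric and the bands
`Plump [0, 0.5)`, `Approximately Plump [0.5, 0.8)`, `Fully Plump [0.8, 1]`
partition the codomain totally; boundary values go to the upper band. Note
the band names run counter to intuition — "Plump" is the *least* globose
group — and are kept as used in practice. Reports pool percentages over
all boxes by default; per-image averaging is available (`by_image = TRUE`)
since the two differ whenever box counts differ across images.

## Evaluation

`iou()` is intersection over union under the package's half-open pixel
convention. Matching is greedy in descending score order with an IOU
threshold of 0.5 (the detection-literature standard; exhaustive optimal
assignment can exceed greedy by at most one match, which the tests verify
on enumerated small configurations). Accuracy is
`(TP + TN) / (TP + TN + FP + FN)`; because pure detection has no natural
true-negative region, TN is operationalised as 64 px background grid cells
touching neither predictions nor truth, and this protocol is carried in
`match_spec()` and reported with every accuracy figure. The F-measure is
the harmonic mean of precision and recall; `art()` is total time over
image count; `count_statistics()` gives the Pearson R and mean-normalised
RMSE between detected and manual counts.

`run_robustness_experiment()` repeats the tiny pipeline across
training-set sizes (retraining per level) or illumination clusters. For
illumination, each repeat trains one model on scenes spanning all five lux
clusters — as a field training set captured under changing light would —
and evaluates it on matched test geometry re-rendered at each level, so
level differences are purely photometric.

## What the synthetic tests do and do not show

The generator emulates the *structure* of the problem: dense small
targets, controlled aspect ratios, fruit–fruit adhesion, leaf occlusion,
and a monotone illumination ladder. Passing tests therefore demonstrate
that the pipeline's machinery is correct — counts are exact, geometry is
tight, training reduces its loss and beats a random-box baseline,
refinement recovers dropped regions without losing recall, grading
recovers the bands it was promised.

They do not demonstrate field performance. Three gaps matter most: the
renderer's low-light scenes are noiseless contrast reductions, not noisy
under-exposures, so illumination effects at desk scale are weaker than (and
can even run opposite to) field behaviour, where brighter scenes also make
the red-tinged soil more fruit-like; superellipse fruit lack the texture,
specularity and calyx of real berries; and the tiny detector is trained
from scratch for minutes, not transfer-learned for hours, so its precision
(duplicate suppression) is far below a converged field model. Absolute
field metrics (accuracy ≈ 0.86, IOU ≈ 0.89) are consequently out of scope
here; the package's experiment harnesses measure directions and machinery,
not those absolute numbers.

## Problem sizes used by the shipped tests

The test-suite and the acceptance script run entirely on synthetic data:
augmentation counts on 400 scenes at 64 x 64; detector learning on 50
scenes / 20 epochs (about a minute of CPU); post-processing direction on a
30-scene adhesion suite with the oracle detector; illumination direction
with 2 repeats of mixed-light training at 30 scenes / 15 epochs. These
sizes were chosen as the smallest that give stable directions over seeds.
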