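---
title: "Methods: a lightweight anchor-free cattle pose estimator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a lightweight anchor-free cattle pose estimator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cattlepose)
```

## The problem

Monitoring cattle behaviour — lameness, recumbency, oestrus — starts from
pose: the positions of 16 anatomical keypoints (head top, neck, spine, the
four thigh-root/knee/hoof triplets, and the coccyx) on each animal in an
image. Heatmap-based pose estimators are accurate but heavy; the model
family implemented here is a single-stage, anchor-free detector that
predicts boxes and keypoints in one pass, with two additions that keep the
network small:

* **SimAM**, a parameter-free attention operator inserted after the C2f
  block of the P3, P4 and P5 backbone stages, and
* an **EfficientRepBiPAN** neck: bidirectional multi-scale fusion built
  from reparameterizable multibranch convolution units (RepBlocks) and
  three-level fusion units (BiFusion), which collapses at inference into a
  chain of plain 3×3 convolutions.

This package implements the full architecture, the OKS/AP evaluation
protocol, the annotation formats, a synthetic scene generator with exact
ground truth, and a small CPU training loop, so every component is testable
without the original farm imagery or a GPU.

## SimAM: energy-based neuron weighting

For a channel with `M = H × W` activations, let `μ` and `σ²` be the channel
mean and population variance (all neurons pooled, the O(M) form; computing
the statistics with the target neuron excluded is O(M²) and changes the
result only at order 1/M — the pooled form is the one the closed-form
energy minimization is derived under, and the excluded variant exists in
the test suite as an oracle). Each neuron `t` receives the importance

$$\frac{1}{e_t} = \frac{(t-\mu)^2}{4(\sigma^2+\omega)} + \frac12,$$

bounded below by ½, and the map is refined as `x · sigmoid(1/e_t)`. The
sigmoid bounds the weights in `[sigmoid(½), 1)` without reordering them.
`ω` (default `1e-4`) regularizes constant channels. The operator holds no
learnable parameters, so inserting it cannot change a model's parameter
count — a property the test suite asserts by counting. Statistics are
computed per channel and per sample, never across a batch.

## Structural reparameterization

During training each RepBlock unit is a sum of three branches — 3×3
convolution + batch norm, 1×1 convolution + batch norm, and (when input and
output channels match at stride 1) an identity batch norm — followed by a
ReLU. At inference the branches fuse exactly:

* batch norm folds into the preceding convolution
  (`W' = Wγ/√(σ²+ε)`, `b' = β − γμ/√(σ²+ε)`),
* a 1×1 kernel embeds into the centre tap of a 3×3 kernel,
* the identity becomes a Dirac kernel,

and the three 3×3 kernels and biases sum into one convolution. Equivalence
is exact up to floating-point accumulation order; the tolerances used in
the tests (1e-5 for a unit, 1e-4 through a whole network) allow for
single-precision-style drift even though all arithmetic here is double.
Fusion strictly decreases the parameter count and never changes shapes or
strides. Fusing an already-fused unit, or a model in training mode, is a
state error: batch-norm statistics must be frozen for the algebra to be
meaningful.

## Architecture and accounting

The backbone is the standard n-scale layout (stem, four C2f stages, SPPF)
with width multiplier ¼, depth multiplier ⅓ and a 1024-channel cap; the
pose head carries, per pyramid level, a distributional box branch
(4 sides × 16 bins), a class branch, and a 48-value keypoint branch
(16 keypoints × x, y, visibility). The baseline configuration uses the
conventional PAN neck; assembling it and counting every learnable scalar
gives 3,274,403 ≈ 3.27 M parameters, and 9.09 GFLOPs at a 640×640 input.

FLOPs here are pinned to a stated convention, because "floating-point
operations" is otherwise ambiguous: one multiply-accumulate counts as two
operations, counted over convolution-type layers (convolutions, transpose
convolutions, the head's 1×1 projections) at batch 1; normalization and
activations are excluded. Parameter counts include convolution kernels,
biases and batch-norm scale/shift pairs; the fixed expectation weights of
the distributional-box projection are not learnable and are not counted.

The internal channel widths of the bidirectional neck are not fully
determined by the architecture description, so they are a design choice of
this package. They were chosen once, committed as the reference
configuration (`inst/configs/improved_n.yaml`: reduce widths 48/32,
bottom-up down-path widths 64/160, neck outputs 48/128/256, one unit per
RepBlock), and frozen. On the fused inference topology this yields
3,106,147 ≈ 3.11 M parameters and 8.10 GFLOPs at 640×640 — 0.17 M
parameters and 0.99 GFLOPs below the baseline. Improved-model statistics
are always quoted on the fused topology, since that is the network that
runs at inference; conv + batch-norm pairs outside rep units are left
unfused so that the baseline's statistics describe its standard form.

The neck's P3 output is 48 channels (the baseline's is 64); the head's
hidden widths adapt to their input (`c2 = max(16, ch/4, 64)`,
`c3 = max(ch, classes)`, `c4 = max(ch/4, 48)`), which is where most of the
computation saving comes from: the P3 level runs on 6,400 of the 8,400
grid cells.

## Evaluation protocol

Object keypoint similarity between a ground truth and a prediction is

$$\mathrm{OKS} = \frac{\sum_i \exp\!\big(-d_i^2 / (2 s^2 k_i^2)\big)\,[v_i>0]}{\sum_i [v_i>0]},$$

with `d_i` the Euclidean pixel error, `s = √(box area)` of the ground
truth, and `k_i` a per-keypoint decay constant. Published per-keypoint
constants exist only for the human skeleton; for the cattle schema the
package defaults to a uniform `k = 0.1`, overridable as a 16-vector.
Visibility codes follow the 0/1/2 convention (not labeled / labeled but
occluded / visible); both 1 and 2 count as observed for OKS.

Matching is greedy: predictions in descending score order (ties broken by
input position) each claim the unclaimed ground truth maximizing OKS;
unmatched predictions carry OKS 0. AP at threshold `t` is the fraction of
detection records with OKS ≥ t — the direct reading of the protocol's
accuracy definition, not the precision-recall-integrated variant — and
AP~0.5:0.95~ averages the ten thresholds 0.50–0.95 in steps of 0.05.
Detections are pooled across images rather than averaged per image; both
choices are computable from the match tables, and pooling keeps small
per-image detection counts from quantizing the result. For isotropic
Gaussian keypoint jitter of standard deviation τ the expected OKS has the
closed form `1 / (1 + τ²/(s²k²))`, which the test suite verifies by
simulation at 10,000 draws — this is the package's strongest end-to-end
check that the metric is implemented exactly.

## Synthetic scenes

The generator emulates the study conditions, not their photographs: 1–3
flat-shaded quadruped silhouettes per image over a textured background,
with scale classes (instance height 45–75 % of the image for "large",
10–25 % for "small"), bright/dim lighting (dim multiplies intensities by
0.35 and adds noise — repository constants, not field measurements),
side/front/back views with view-consistent visibility flags (far-side
limbs, hindquarters or forequarters labeled-but-occluded), vertical fence
bars that overdraw the animals and flip covered keypoints to occluded,
inter-animal occlusion by draw order, and optional edge truncation
(off-canvas keypoints become unlabeled). The default factor mixture
follows the study's condition breakdown: large:small 2:1, bright:dim 1:1,
views equal, occluded:unobstructed 1:2, and 1–3 animals per image at
proportions giving ≈1.26 instances per image.

Because keypoints and silhouettes come from the same parametric skeleton,
annotations are exactly consistent with the rendered geometry — every
visible keypoint lies on its instance's foreground mask, which the tests
check by lookup. What passing tests on these scenes cannot show is
robustness to real-image nuisances: breed appearance, barn backgrounds,
motion blur, perspective foreshortening. The generator validates geometry,
formats and metrics, not visual realism.

## Training at desk scale

The training loop exists to exercise the architecture end to end, not to
reproduce any accuracy figure. It follows the published schedule — SGD,
momentum 0.937, weight decay 5e-4, batch 32 (16 in the test suite's smoke
run), learning rate 0.01 decaying linearly to 1e-4, 3 warm-up epochs, and
mosaic augmentation disabled for the final 10 epochs. The warm-up "0.1"
setting is interpreted as the bias-group starting rate (the family's
convention); warming *all* parameters up at ten times the initial rate
would contradict the rate being "restored" to 0.01 afterwards.

Design choices where the family's full machinery was out of proportion for
a desk-scale loop, with their rationale:

* **Assignment** is center-cell (one positive cell per ground truth, on
  the level whose stride best matches the box size) rather than
  task-aligned dynamic assignment. With 1–3 large, well-separated
  instances per synthetic image, dynamic assignment changes little and
  costs much.
* **Box loss** is the distributional cross-entropy term alone; the
  complete-IoU term is omitted. The expected-distance decode is already
  driven to the target by the distribution term.
* **Keypoint loss** is the OKS-kernel form `1 − exp(−d²/(2s²(2k)²))` plus
  a small quadratic pull (`0.05 · d²/s²`). The widened kernel and the
  quadratic term keep gradients alive when predictions start far from the
  target, where the evaluation kernel is flat; evaluation always uses the
  unwidened `k`.
* Loss gains are the family defaults (box-distribution 1.5, class 0.5,
  keypoint 12, visibility 1).

The reverse-mode engine underneath is a tape of array operations
(im2col-based convolution, transpose convolution, batch norm, SiLU/ReLU,
pooling, concatenation, and the attention operator with its analytic
gradient); every operator is validated against central differences in the
test suite. Batch statistics are population-form; running statistics use
momentum 0.03 and ε = 1e-3.

Problem sizes in the shipped tests were chosen to make the suite a
desk-scale object: the end-to-end smoke run trains the improved topology
at width multiplier 0.125 on 200 synthetic 64×64 scenes for 50 epochs,
asserting strictly decreasing smoothed loss (10-epoch block means) and
that post-training reparameterization moves validation metrics by less
than 1e-3. "Best parameters" during training are selected by validation
AP~0.5~, the headline metric.

## Numerical and degenerate-input choices

* Channels with a single neuron (`H·W = 1`) make the attention variance
  undefined; they raise a degenerate-input error rather than returning 0.
* OKS against a ground truth with no visible keypoints (or a zero-area
  box) is undefined and raises an error; `ap_at` of an empty match table
  is 0 by convention.
* Inputs not divisible by 32 are rejected at the stem; the stride
  contract (P3/P4/P5 at 8/16/32) is asserted for valid sizes.
* Box side-distances are clamped to `[0.01, 14.99]` bins before building
  distribution targets; keypoint decode uses the cell-relative
  `2·raw + (anchor − 0.5)` convention times the stride.
* Greedy NMS breaks score ties by input order; matching does the same.
* Split sizes are `round(n · ratio)` against the shuffled manifest, so the
  same seed always reproduces the same split.

## Known limitations

* No GPU path and double precision only: training beyond toy scale is far
  slower than the PyTorch ecosystem this architecture normally lives in.
* The synthetic scenes cannot certify accuracy on real cattle imagery;
  accuracy numbers from the original study are out of reach by design.
* Per-keypoint OKS decay constants for cattle are unpublished; the uniform
  default makes absolute OKS values comparable only within this package's
  conventions.
* Grouped convolutions are supported in inference (needed for Dirac-kernel
  checks) but not in the gradient path; no architecture in the package
  uses them trainably.
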