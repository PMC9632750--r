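---
title: "Methods: imbalance-corrected fusion networks for lesion classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imbalance-corrected fusion networks for lesion classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionfuse)
```

## The problem and the model

Pigmented-lesion archives are dominated by benign nevi: in HAM10000 the `nv`
class holds 66.95% of the 10,015 images, and the rarest class
(dermatofibroma) has 115. Training a softmax classifier directly on such data
yields a majority-class predictor. `lesionfuse` treats the imbalance in data
space — rotation and style-transfer upsampling that *exactly balance* the
per-class counts by construction — and strengthens the classifier by fusing
three convolutional backbones under attention, trained with a two-phase
transfer-learning protocol.

### Preprocessing

Images are resized to a fixed target (default 450 rows x 600 columns,
nearest-neighbour interpolation with the top-left origin, row-major), then
intensities are min-max normalized. The default normalization uses the global
8-bit range (`X_min = 0`, `X_max = 255`): dividing every image by the same
constant preserves the contrast relations *between* images, which per-image
scaling would destroy. A per-image mode is kept behind a flag for
completeness; its degenerate case (a constant image, max equal to min) maps
to an all-zero image rather than erroring. Resizing precedes normalization;
for nearest-neighbour interpolation the order is observationally irrelevant,
but fixing it makes runs byte-reproducible.

### Rotation upsampling

Every record of every non-majority class is joined by its left-right mirror,
its up-down mirror and their composition (the 180-degree rotation), a 4x
multiplication. All originals are retained for all classes, including the
majority class — dropping majority originals would shrink the training set
for no benefit and contradicts the count bookkeeping below.

### Style-transfer allocation and execution

With post-rotation counts `n_i` and the majority count `N`, the upsampling
ratio is `Add_i = (N - n_i) / n_i`:

* `Add_i >= 1`: every image of class *i* is a content image and spawns
  `floor(Add_i)` styled images; the class ends at `n_i * (1 + floor(Add_i))`.
  Flooring is deliberate and the residual deficit is *not* topped up — the
  count identity `n_after = n_before * (1 + num_add)` is what the plan
  promises and what `execute_plan()` realizes exactly.
* `Add_i < 1`: exactly the deficit `N - n_i` of content images, chosen
  uniformly without replacement, each spawn one styled image, topping the
  class up to `N` exactly.

Style sources are drawn from the *same class* (style transfer is a
within-class recombination, not a cross-class contamination), excluding the
content image itself; when a class is smaller than the number of styles
requested, sampling falls back to replacement with a warning rather than
failing the run. On data with mild imbalance the 4x rotation stage can push a
minority class above the original majority; the pipeline therefore computes
the allocation against whichever class holds the post-rotation maximum.

The stylizer itself is pluggable. The default backend is a first-principles
statistical colour/texture transfer: content and style are mapped to a
decorrelated luminance/chrominance space (BT.601 YCbCr), each channel of the
content is affinely rescaled to the style's mean and standard deviation,
blended by `strength` (default 1, maximizing sample diversity), mapped back
and clipped to gamut. A zero-variance style channel keeps the content's
statistics. Any external neural stylizer can be registered under a name and
selected in the configuration without touching the planner, because the count
semantics live entirely in the plan.

### Comparison arms

Two alternative imbalance treatments are implemented as mutually exclusive
strategies, for ablation rather than recommendation: inverse-frequency class
weights `w_i = n_samples / (n_classes * n_i)` applied to the loss (these
satisfy `sum(w_i n_i) = n_samples`, so a balanced batch reduces to the
unweighted loss), and pixel perturbation, which clones images shifted by an
8-bit magnitude drawn without replacement from `[1, floor(gap / (2K))]` with
random sign, clipping at the gamut; the pool resets with a warning when
exhausted. Perturbation gaps are measured against post-rotation counts,
matching the pipeline order in which the scheme is applied.

## Fusion architectures

For a 450x600x3 input the three standard backbones emit feature maps of
(12, 17, 2048) (Inception V3), (12, 17, 1536) (InceptionResNet V2) and
(14, 19, 2048) (Xception). The package encodes each architecture layer by
layer, so these dimensions are *derived* from the convolution size arithmetic
`W_out = (W_in - F + 2P)/S + 1` (with the framework floor/ceil conventions
for valid/same padding) rather than asserted; the same builders reproduce the
native 8x8/10x10 maps for 299x299 inputs.

Three fusion strategies are provided:

* **conv_reduce** — branches with the larger spatial map pass through one
  valid 3x3 stride-1 convolution (mapping 14x19 onto 12x17), keeping the
  source branch's channel count (the only free choice; the kernel, padding
  and stride are fixed by the dimension equation), then channel-axis
  concatenation, CBAM, global average pooling (GAP), a dense layer and a
  softmax head. An irreconcilable mismatch is a hard error that names the
  offending branch and suggests zero-padding.
* **zero_pad** — smaller maps gain rings of zeros (12x17 to 14x19 with one
  ring) up to the largest spatial dims; padding adds no activation mass, so
  GAP-level statistics are diluted but never distorted.
* **dense_concat** (classifier-level) — each branch keeps its own CBAM, GAP
  and dense feature vector (width `branch_dense_units`, default 256;
  desk-scale configurations use smaller values) plus an auxiliary softmax
  head; the merged head concatenates the three dense vectors. The model
  exposes four outputs and the training loss is the *unweighted sum* of the
  four cross-entropies; the merged output is the model's prediction.
* Elementwise sum/mean/max fusion is available when all branch maps agree in
  shape; shape identity is enforced as a hard error because it is the
  defining constraint of parallel fusion.

CBAM is inserted after each backbone's final convolution and before GAP:
channel attention first (a shared two-layer bottleneck, reduction ratio 16 by
default, applied to the global average- and max-pooled descriptors, summed,
sigmoid), then spatial attention (a 7x7 convolution over the channel-wise
mean and max planes, sigmoid), both multiplicative. With all attention logits
at zero the block scales its input by exactly 0.25 (two half-open gates) — a
useful closed form that the tests exploit. Attention is toggleable per
branch, since single-backbone ablations with and without CBAM are meaningful.

## Training protocol

Phase 1 freezes every node tagged as backbone and trains only the new layers
(attention, dense, heads); phase 2 unfreezes everything. Defaults: Adam,
learning rates 1e-3 (phase 1) and 1e-5 (phase 2), batch size 16, 5 + 20
epochs. The optimizer, rates and epochs are not dictated by the method; they
are configuration with the constraint that the phase-2 rate may not exceed
phase 1's (fine-tuning must not destroy transferred features). Mini-batch
order derives from a dedicated seed stream, so runs are bit-reproducible; a
non-finite loss aborts with a diagnostic rather than training through NaNs.
Class weights and data-space balancing are treated as mutually exclusive
strategies, never combined. A hard-voting ensemble baseline (majority vote,
ties broken by the highest mean predicted probability among tied labels) is
provided for comparison with the fusion heads.

## Evaluation metrics

All metrics derive from the K x K confusion matrix via one-vs-rest counts.
Reported per class: one-vs-rest accuracy `(TP+TN)/n`, sensitivity/recall,
specificity, precision, F1, and midrank ROC AUC (the normalized Mann-Whitney
statistic; ties count one half, verified in tests against exhaustive pair
counting). Weighted averages use test-set supports as weights. Per-class
one-vs-rest accuracy and recall are deliberately reported side by side under
distinct labels — they are different quantities that are easy to conflate —
and the *overall (micro) accuracy* is the headline number. Undefined ratios
(0/0) are reported as 0 with an explicit flag so weighted averages remain
computable; AUC for a class absent from the truth is `NA` and excluded from
the weighted average.

## Saliency

Grad-CAM weights each channel of a chosen convolutional layer by the spatial
mean of the gradient of the target-class score; Grad-CAM++ replaces the mean
with per-location coefficients `alpha = g^2 / (2 g^2 + sum_spatial(A g^3))`
(zero-division guarded to 0) and weights `sum(alpha * relu(g))`. The
rectified weighted channel sum is min-max normalized to [0, 1]; an all-zero
rectified map is returned as zeros with a flag (no positive evidence) rather
than divided by zero. Gradients are taken with respect to the *pre-softmax
score* of the target class by default — the standard CAM practice, since
softmax gradients entangle all classes — with a probability mode behind a
flag. For classifier-level fusion, per-branch maps are computed against the
merged output, so each map shows that backbone's contribution to the final
call; the visualized layer defaults to each branch's last convolutional stage
after attention. Heatmaps are upsampled bilinearly (center-aligned) for
overlay rendering under a fixed colour ramp.

## The neural-network engine

No deep-learning framework is a dependency: a compact layer-graph engine in
base R implements the forward and backward passes of every operation the
models need (convolution via cached gather/scatter index maps and BLAS
matrix products, depthwise convolution, max/average/adaptive-average/global
pooling, dense layers with optional weight sharing for the CBAM bottleneck,
channel pooling, broadcast gating, concatenation, zero-padding, softmax,
cross-entropy, Adam). Parameters are Glorot-uniform initialized under a seed.
Every gradient path is checked against central finite differences in the test
suite (tolerance 1e-4 relative for parameters at epsilon 1e-5; saliency
weights at 1e-3 relative). Test models use smooth activations where finite
differences are involved, because FD at a ReLU kink is ill-posed — a property
of the mathematics, not of the implementation.

Full-size numeric passes through the standard backbones are possible in
principle but pointless in pure R; the architecture builders are therefore
exercised numerically through tiny randomly initialized stand-ins
(`tiny_backbone()`: two stride-2 convolutions and an adaptive average-pooling
stage emitting any requested map shape, including the 12x17-vs-14x19 mismatch
case), while the full-size builders are exercised at the shape level, which is
exactly the quantity the dimension arithmetic determines.

## The synthetic benchmark

`synthetic_spec()`/`generate_dataset()` emulate the *structure* of the
dermoscopy problem: HAM10000's per-class counts (scaled by any factor,
rounded, floored at 2 so a 3:1:1 stratified split stays feasible), skin-toned
backgrounds with Gaussian noise, one roughly elliptical lesion per image with
jittered centre and semi-axes, sinusoidal border irregularity, and a
class-specific hue (evenly spaced hues by default, hence disjoint). Hue
separation makes the classes learnable by a tiny network, which is the point:
a pipeline wiring bug (label shuffling, frozen-everything training, a dead
fusion path) would show up as chance-level accuracy. What the generator does
*not* emulate: real lesion morphology and texture, hair and ruler artifacts,
within-class colour overlap, inter-device colour shifts. Passing desk-scale
tests therefore demonstrates mechanical correctness of the pipeline, not
clinical performance; the headline metrics of full-scale dermoscopy training
are outside this package's test envelope.

At very small scales a class with only 2 members splits 1/1/0 under 3:1:1
(floor-and-distribute, remainders to the largest fractional part, ties
resolved in part order); training and validation stay non-empty, and the
evaluation suite tolerates classes absent from the test split (`NA` AUC,
excluded from weighted averages).

## Numerical choices and degenerate inputs

* Stratified splitting: per-class floor-and-distribute rounding keeps every
  part within one record of its exact proportion; a class with zero members
  is a hard error.
* Probability columns are clamped with epsilon 1e-9 inside the cross-entropy
  only; reported probabilities are the raw softmax outputs (columns sum to 1
  within 1e-6 in tests).
* `same` padding follows the asymmetric convention of the mainstream
  frameworks (extra cell at the bottom/right); `valid` uses
  `floor((in - k)/s) + 1`. The exported `conv_output_dims()` enforces the
  exact divisibility of the textbook formula and errors otherwise, naming the
  offending dimension.
* Max-pool and max-fusion tie-breaks take the first maximum in column-major
  order; deterministic, and irrelevant at float precision.
* All randomness flows through per-task seed streams that save and restore
  the global RNG state, so library calls never perturb a user's session RNG.

## Desk-scale problem sizes

The test suite and the bundled configurations run at deliberately small
sizes chosen as the package's own test envelope: 16x16 to 32x32 images,
tiny backbones with 4-8 channel maps, batch sizes 8-25, and a 2%-scale
synthetic archive (200 images) for the end-to-end run. The full-scale count
arithmetic (about 29,000 records after augmentation) is exercised with
6x8-pixel images, since the count identities are independent of image size.

## Known limitations

* The statistical colour-transfer backend matches first and second moments
  only; it does not transfer texture the way a neural stylizer does. The
  backend registry exists precisely so a stronger stylizer can be swapped in.
* The engine is single-threaded pure R: suitable for desk-scale verification
  and method development, not for full-resolution training.
* Batch normalization is not modelled; the standard-backbone builders encode
  the convolutional skeleton (all shape-determining layers), which is
  sufficient for dimension analysis and for transfer-learning structure, not
  for loading published pretrained weights.
* Grad-CAM++ alpha coefficients follow the stated formula with a guarded
  denominator; no per-channel renormalization of alpha is applied.
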