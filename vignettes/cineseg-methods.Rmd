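---
title: "Recurrent dual-output segmentation of thyroid ultrasound cineclips: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recurrent dual-output segmentation of thyroid ultrasound cineclips: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

A thyroid ultrasound exam records a *cineclip*: a video sweep of the
transducer across the neck in the transverse plane. `cineseg` implements a
complete framework for semantic segmentation of such sweeps — thyroid gland,
solid nodules and cysts — built around three ideas: a **dual-output**
convolutional network (a sigmoid head for the gland and a softmax head for
lesions, so a nodule need not be carved out of the thyroid mask), a
**bidirectional dilated ConvLSTM module** that integrates evidence across
neighboring frames of the sweep, and a **class-balanced Matthews-correlation
loss** that stays informative on the overwhelming majority of frames that
contain no lesion. Because clinical cineclips are private, the package ships
a speckle-phantom simulator with exact ground truth; every result the test
suite and the acceptance script report is computed on those phantoms.

## The segmentation models

### Backbone

The static (frame-wise) model is a dilated residual network in the
DeepLabv3+ style:

* an input stem of three 3×3 convolutions (32, 32, 64 filters; the first
  strided by 2) followed by 3×3/stride-2 max pooling — the "ResNet-C" stem;
* four bottleneck stages of `CB` (projection) + `IB` (identity) blocks with
  filter triples [64 64 256], [128 128 512], [256 256 1024], [512 512 2048]
  and identity-block repeats (2, 4, 23, 2). Stages three and four replace
  their stride by dilation rates 2 and 4, keeping the deep features at
  output stride 8. (The published block table lists the stage-two projection
  block as `[128 128 256]`, which cannot be residually added to the
  following `[128 128 512]` identity blocks; we use 512, the standard
  ResNet101 value.) All activations are LeakyReLU with slope 0.10; every
  convolution is followed by batch normalization;
* an atrous spatial pyramid pooling (ASPP) module: parallel 1×1, three
  dilated 3×3 branches, and a global-average-pooling image branch, each with
  256 filters, concatenated and projected back to 256;
* four skip-fusion blocks: each skip (stem pool, stage-1, stage-2, stage-3
  outputs) and the running main path pass through 1×1 convolutions of 128
  filters, are spatially aligned by bilinear resize **to the shallower
  (larger) size**, concatenated, normalized and activated. After fusing the
  stride-4 skips the fused feature map lives at 1/4 of the input
  resolution.

A `width_multiplier` scales every filter count (as `ceiling(n·w)`, floored
at 1), giving a desk-size instantiation at `w = 1/8` whose convolutional
core parameter count scales as `w²`.

### Output heads

Each head is a single transposed convolution (1 filter for the sigmoid
thyroid head, 3 for the softmax background/cyst/nodule head) followed by a
1×1 convolution and the activation. We use kernel 8 / stride 4, which
restores the input resolution exactly from the stride-4 fused map with full
output coverage. The alternative sometimes quoted for this architecture —
kernel 4 with stride 8 — is available behind `head_kernel`/`head_stride`
but is not the default for two mechanical reasons: from a stride-4 feature
map it produces twice the input size, and a kernel smaller than its stride
leaves 3/4 of output pixels connected to nothing but the bias.

### Recurrent module

For the sequence model the trained static network is **frozen**, its heads
removed, and its fused feature map replicated over a window of 6 frames.
The leading half-window forms a *forward group* and the trailing half a
*backward group*. Each group stacks four bidirectional ConvLSTM blocks at
dilation rates 1, 3, 5 and 7; a block pairs a forward-time and a
backward-time ConvLSTM (3×3 gate kernels, 32 filters at width 1, scaled by
the width multiplier), concatenates their outputs, and applies batch
normalization and LeakyReLU. A final forward ConvLSTM summarizes the
leading group and a final backward ConvLSTM the trailing group; their
terminal states are concatenated, normalized, and drive fresh dual heads.
The census is exactly 2 groups × 4 blocks × 2 + 2 = **18 ConvLSTM layers**.

The window emits one segmentation, assigned to the *current frame* at
index `window/2` (frame 3 of 6): the prediction conditions on the frames
before it through the forward group and on the frames after it through the
backward group, matching the idea of sharing features from the surrounding
frames before emitting the current frame's map. `segment_cineclip()`
slides the window one frame at a time with edge replication, so every frame
of a clip receives exactly one prediction. ("Backward" application of a
ConvLSTM means running it on the time-reversed sequence and re-reversing
the outputs; normalization inside the module treats time steps as batch
entries.)

Weight initialization is He-uniform for convolutions and orthogonal for the
hidden-to-gate ConvLSTM kernels, with a +1 forget-gate bias; everything is
seeded and construction is a pure function of (config, seed).

## The class-balanced MCC loss

With per-pixel probabilities `p` and binary targets `y`, soft confusion
counts are `TP = Σ p·y`, `FP = Σ p(1−y)`, `FN = Σ (1−p)y`,
`TN = Σ (1−p)(1−y)`, and the Matthews correlation coefficient is

```
MCC = (TP·TN − FP·FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN) + ε)
```

with `ε = 1e−6` inside the root. A subtle but decisive point shapes our
formulation: a *per-class, one-vs-rest* soft MCC is **identically zero for
any class absent from the truth** — `y = 0` everywhere forces
`TP = FN = 0`, so the numerator and its gradient vanish for every possible
prediction. A loss built that way could not prefer a correct all-negative
prediction over a confident false positive on a lesion-free frame, which is
precisely the situation that dominates cineclip training (no lesion in
~65% of frames). We therefore aggregate the soft counts **within each
output head, over pixels and over the head's classes**, weighting each
class's counts by a class weight: the sigmoid head contributes channels
`(p, 1−p)` with the thyroid and background weights, the softmax head its
background/cyst/nodule channels. One MCC is evaluated per head and the
loss is `1 − mean(MCC_heads)`. On an all-background frame this aggregate
reaches +1 for correct silence and −1 for a confident inversion, with
finite nonzero gradients everywhere — the property that distinguishes the
MCC loss from overlap losses such as Dice, which return zero either way.

Default class weights are inverse pixel frequencies computed on the
training split, with the two majority classes (background, thyroid)
multiplied by 0.1 and the whole vector normalized to unit
frequency-weighted mean. On phantom cohorts this weighting reproduces the
clinically reported behavior of frequency up-weighting: high lesion recall
with a tendency to over-segment (precision well below recall).

## Four-stage training

1. **Stage 1** — the single-output thyroid model trains on the pretrain set
   (pretrain ∪ train splits) with frame batches.
2. **Stage 2** — the lesion head is added (all other layers shared by
   reference with stage 1) and the dual-output model trains on the train
   split. Batches are drawn by the *forced-nodule sampler*: with
   probability 2/3 a batch contains only nodule-bearing frames, otherwise
   frames are uniform. (The published description "two batches chosen to
   include a nodule for every three batches" is read as 2-of-3; the ratio
   is a config knob, as are the alternative subsample-to-60% and
   duplicate-oversampling policies.)
3. **Stage 3** — everything through the ASPP module is frozen and the
   remaining output layers (skip fusion + heads) train on full sequences,
   applied frame-wise by the static model.
4. **Stage 4** — the recurrent model is built on the frozen backbone and
   the ConvLSTM module plus fresh heads train on full sequences; fused
   feature maps are precomputed once per clip per epoch (the backbone does
   not update), and supervised windows draw their current frame uniformly
   over the sweep with the same clamped edge-replicated windows inference
   uses.

Augmentation follows the published per-stage table (flip 50%; rotation
25%/±15° in stage 1 and 50%/±5° in stage 3; translation 25%/±10%;
intensity shift 10%/±5% applied to tissue pixels only — the −1 padding
sentinel is never touched; crop at 300 or 256 px, capped at the canvas, so
it is a no-op on small phantoms; stage 4 uses flip and 50% sequence
reversal). Geometric transforms use bilinear resampling for frames and
nearest-neighbor for labels, and bilinear values contaminated by the
sentinel snap back to −1.

Optimizer defaults are Adam with step 1e−3 for stages 1–2, 1e−4 for
stage 3, and 3e−3 for stage 4 — the recurrent module and its heads train
from scratch on frozen features and tolerate (and need) the larger step.
Epoch counts are configuration; `tiny_protocol_plans()` uses 5/5/2/15
epochs, sized for a width-1/8 model on 64×64 phantoms. Per-epoch history
records the loss; validation IoU is computed at the cadence
`validate_every` (default: final epoch only, to keep desk runs fast).
Training is bit-reproducible given the plan seeds.

### Study conditions used by the tests and the acceptance script

The end-to-end experiments train on a 20-patient, 12-frame, 64×64 phantom
cohort split 60/20/20 by patient, width 1/8. The temporal-benefit
comparison then evaluates both the stage-2 static and the stage-4
recurrent model on a 6-clip *flickered* cohort (`flicker_prob = 0.35`,
contrast residual 0.15): lesions are intermittently rendered at 15% of
their contrast while the ground truth retains them, emulating transient
obscuration as structures pass the imaging plane. A frame-wise model
cannot see an obscured lesion; the recurrent window carries it across
frames, and the paired per-clip nodule IoU difference (recurrent − static)
is the reported benefit. Three seeds are run and medians reported.

## Synthetic sweep phantoms

A phantom is a set of static 3-D ellipsoids (a thyroid band plus lesions)
sliced by the imaging plane at uniform velocity — structures grow, shrink
and enter/leave the view exactly as in a clinical sweep, and because the
sweep velocity is constant the slice-integral volume of any structure is
known in closed form. Echogenicity maps to mean reflectivity (anechoic
cysts ≈ 0; hypo/iso/hyper nodules at the thyroid level ∓ a contrast
offset); ill-defined margins blur the reflectivity edge (never the mask);
lobulated margins modulate the boundary radius by `1 + a·sin(mθ)` with
`a ≤ 0.3`, `m ∈ 3..6`. Frames are reflectivity × Gamma(shape k, mean 1)
multiplicative speckle, clipped to [0, 1]; the default shape 4 gives
B-mode-like granularity. Masks are exact, noise-free geometry and are
identical across seeds for fixed geometry — flicker and speckle perturb
frames only. An optional dark vessel tube (a cyst confounder) and a
`thyroid_z_exponent` are available; the latter flattens the gland's
cross-section profile along the sweep into a band (exponent 4), which is
how a real gland presents — its cross-section does not shrink
elliptically over the sweep.

Cohort generation draws per-patient geometry so the pooled statistics hit
the clinical anchors — nodules in ≈35% of frames and ≈2% of pixels (the
nodule's sweep extent comes from the frame target and its in-plane area
from the pixel target); cysts at half the nodule rate, anechoic; synthetic
pathology strata including one rare cohort so stratified splitting is
exercised.

What the phantoms do **not** model: the physics of ultrasound formation
(no point-spread function, attenuation, shadowing or time-gain
compensation), diffuse disease texture (Hashimoto, Graves), probe-geometry
scan conversion, or operator-dependent sweep speed. Passing tests on
phantoms demonstrate that the machinery — architecture, loss, protocol,
metrics — behaves as designed on data with the right statistical
structure; they are not evidence of clinical-grade accuracy.

## Volume estimation

`integral_volume()` sums slice areas times spacing (`dz` defaults to one
frame-unit under the uniform-velocity assumption);
`ellipsoid_volume(L, W, H) = π/6·L·W·H` is the clinical caliper
approximation, applied to the per-class bounding extents; and
`percent_difference = 100·(ellipsoid − integral)/integral`, so negative
values mean the caliper formula underestimates. Two geometric facts govern
the sign, and both are verified by tests: sinusoidal in-plane lobulation
*inflates* the calipers (protruding lobes stretch the bounding box without
filling it), so for an isolated lobulated nodule the formula
overestimates; a band-shaped gland fills its bounding box more fully than
an ellipsoid, so for the thyroid the formula underestimates — by roughly
−25% on band-profile phantoms, the direction reported for clinical
glands. On true digitized ellipsoids both estimators agree with the
analytic volume to well under 2% (volume experiments use half-integer
grid centring, which removes an asymmetric one-voxel caliper bias).

## The distance-regularized level-set baseline

The seeded baseline evolves a level-set function by distance-regularized
level-set evolution: a double-well distance-regularization term (weight
`μ = 0.2/Δt`, the method's stability rule, implemented in the stable
`div((d_p−1)∇φ) + Δφ` form), an edge term
`λ·δ_ε(φ)·div(g·∇φ/|∇φ|)` and a balloon term `α·g·δ_ε(φ)`, with the edge
indicator `g = 1/(1 + |∇(G_σ∗I)|²)` computed on the σ = 1.5 smoothed image
with the squared gradient normalized by its maximum (×100), making the
result invariant to intensity scaling. Parameters default to the
grid-searched values reported for seeded thyroid segmentation: Δt = 1,
λ = 1, α = −0.9, ε = 2.75, 60 outer iterations (of 10 elementary steps
each, the reference implementation's inner loop) plus 10 balloon-free
refinement steps. Seeds are ground-truth masks dilated by an exact
Euclidean disk (radius 20).

Three numerical choices matter and are documented here because the method
is sensitive to them. First, φ is **positive inside** and the output is
`{φ > 0}`; with the evolution equation unchanged this makes α = −0.9
contract the (oversized, dilated) seed toward the boundary, the only
direction consistent with seeding by dilation. Second, φ initializes as
the **signed distance** to the seed rather than a binary step: with
ε = 2.75 a ±2 step keeps the smoothed Dirac alive over the whole interior
(deflating φ globally), and any step profile moves an order of magnitude
slower than the balloon speed until the regularizer has rebuilt a distance
profile — which at these parameters it never fully does. Third, φ is
**reinitialized** to a signed distance every 5 outer iterations: at the
weak edge weight λ = 1 the balloon steepens the profile to |∇φ| ≈ 2.4,
which divides the front speed and strands the contour ≈2 px outside the
boundary; with reinitialization the contour converges crisply (clean-disk
IoU ≈ 0.996, insensitive to σ and the normalization constant). On heavily
speckled phantoms the edge indicator is riddled with spurious valleys, the
contour freezes near the dilated seed, and the baseline shows the
characteristic over-segmentation signature — recall ≈ 1 with far lower
precision.

## Numerical engine

No deep-learning framework is available to R in this environment, so the
package carries its own: im2col/GEMM convolution, transposed convolution,
and max-pooling kernels in C++ (RcppArmadillo), batch normalization,
bilinear resizing, a small reverse-mode tape over the op vocabulary the
architecture needs, ConvLSTM with backpropagation through time, and Adam.
Every kernel's adjoint is verified against central finite differences in
the unit tests, and the composite graphs (backbone, recurrent module,
loss) are gradient-checked end to end. Batch-norm uses per-channel batch
statistics with running means for inference (momentum 0.1); frozen
subgraphs run in inference mode and their gradients are skipped entirely.
Determinism: construction and training are pure functions of configs and
seeds; repeated runs agree to within 1e−6.

## Known limitations

* Phantom realism is structural, not physical (see above); absolute metric
  values on phantoms do not transfer to clinical data.
* The lesion heads inherit the over-segmentation tendency of
  inverse-frequency weighting; nodule precision on phantoms is low even
  when recall is high, matching the behavior reported for this weighting
  but limiting the absolute nodule IoU at desk scale.
* The desk-size configuration (width 1/8, 64×64) underfits fine boundary
  detail by design; full-width, 256×256 training is configurable but far
  outside a single-CPU budget.
* `stage 3` trains the static model frame-wise over full sequences; an
  intermediate sequential model is a plausible alternative reading of the
  protocol and is not implemented.
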