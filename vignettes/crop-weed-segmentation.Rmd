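---
title: "Corn/weed semantic segmentation: model, data and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corn/weed semantic segmentation: model, data and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Early-season weed management in maize needs a per-pixel separation of three
classes — soil background, corn seedlings, and companion weeds — from
nadir-view field imagery. The two foreground classes are both green, so color
alone cannot separate them; what distinguishes them is scale and shape (large
multi-lobed corn rosettes versus small weed blobs and blades), and the
hard cases are precisely where they overlap and occlude each other. This
package implements an encoder–decoder segmentation network specialized for
that regime, together with the dataset tooling, augmentation protocol,
Dice-loss training loop, and confusion-matrix evaluation around it.

## Model

### Baseline U-net

The baseline (`preset("unet")`) is a symmetric encoder–decoder: four
down-blocks of two 3×3 convolutions with relu followed by 2×2 max-pooling,
channel widths doubling 64→128→256→512 into a 1024-channel bottleneck; the
decoder mirrors this with 2× upsampling, skip concatenation of the
matching-resolution encoder features, two 3×3 convolutions per layer, and a
final 1×1 convolution mapping 64 features to the class scores. We use
same-padding throughout, so the classic crop-before-concatenate step of
valid-padded U-nets is unnecessary: encoder and decoder resolutions match
exactly, and outputs have the input's spatial size for any side divisible
by 32.

### ResNeXt-50 (32×4d) encoder

`preset("unet_1")` replaces the encoder with a ResNeXt-50: stem (7×7
stride-2 convolution to 64 channels, 3×3 stride-2 max-pool) and four stages
of aggregated-residual bottleneck blocks repeated 3/4/6/3 times. Each block
computes `Y = X + Σ_{i=1..C} T_i(X)` with cardinality `C = 32`: a 1×1
compression to the bottleneck width (128 at stage 2, doubling per stage), a
3×3 *grouped* convolution with 32 groups (width 4 per group at stage 2), and
a 1×1 expansion to twice the bottleneck width. The grouped form is
arithmetically identical to 32 parallel branches whose expansions are
summed; the test suite asserts this equivalence numerically. Downsampling
uses stride 2 on the grouped 3×3 of each stage's first block, with a 1×1
projection shortcut where shapes change. The classification head (global
average pooling + fully connected) is never built — the encoder exists to
feed the decoder's skip connections with a five-level pyramid at strides
2/4/8/16/32 and 64/256/512/1024/2048 channels.

The original block design leaves the normalization layout unstated; we adopt
the reference convention (batch normalization after every convolution,
rectification after the residual sum) because random-initialization training
at learning rate 0.001 is unstable without it. `norm = "none"` builds the
plain affine form, which the arithmetic oracle tests use so that
equivalences hold exactly.

### Deformable convolution in the deepest decoder layer

`preset("unet_12")` replaces both 3×3 convolutions of the deepest decoder
layer (the one consuming the stride-32 features — the most abstract level,
where a larger, shape-adaptive receptive field helps most) with deformable
3×3 convolutions:

`y(P0) = Σ_{P_n ∈ R} w(P_n) · x(P0 + P_n + ΔP_n)`

The offset field `ΔP` has shape H×W×2N (N = 9 taps) and is predicted from
the same input by a side 3×3 convolution whose weights and biases start at
zero, so training begins exactly at the standard-convolution fixed point and
the offsets are refined by backpropagation. Fractional sampling positions
are resolved by bilinear interpolation with a zero-padding convention
(positions outside the grid contribute nothing), consistent with the
zero-padded convolution itself. Conventions frozen for checkpoints: taps
enumerate `{-1,0,1}²` row-major; tap *n* owns offset channels `(2n, 2n+1)` =
(Δrow, Δcol); one offset group shared across input channels, which is what
the H×W×2N offset shape implies. 1×1 and 5×5 deformable kernels are
deliberately not offered: the former cannot enlarge the receptive field and
the latter is disproportionately expensive.

### scSE attention in decoder layers 2–4

`preset("unet_123")` (alias `rds_unet`) appends a concurrent
spatial-and-channel squeeze-and-excitation block after the convolution pair
of decoder layers 2, 3 and 4: `X_scSE = X_csE + X_ssE`. The channel branch
squeezes with global *average* pooling, reduces to half the channels
(reduction ratio fixed at 2 — an explicit design choice here, where the
generic block more commonly reduces further) through a fully connected layer
with relu, recovers the full width through a second fully connected layer,
and gates channels with a sigmoid. The spatial branch gates positions with a
sigmoid over a single-channel 1×1 convolution. Both gates live strictly in
(0, 1), so the summed output is bounded by twice the input elementwise, and
with all parameters zero both gates are exactly ½ and the block is the exact
identity — the test suite asserts this closed form.

Default initialization deviates from all-zero deliberately: zeroing *both*
fully connected weight matrices is a dead fixed point under backprop (the
relu input is identically zero, so neither matrix can receive gradient).
The channel branch therefore starts with small He-scaled random weights and
zero biases, while the spatial 1×1 convolution does start at zero — its
gradient path does not collapse. The attention distortion at initialization
is negligible (gates ≈ ½ up to small fluctuations, and the two halves still
sum to ≈ x).

### Decoder widths

The printed architecture diagram does not specify decoder channel widths. We
mirror U-net's halving convention on the ResNeXt pyramid: concat(upsampled,
skip) is reduced to the skip level's width, giving the 2048→1024→512→256→64
path, then a final 2× upsample and 1×1 head restore full resolution.
Upsampling is bilinear 2× (half-pixel-aligned, edge-clamped) followed by the
layer's convolutions rather than a transposed convolution — either is
admissible; bilinear is deterministic and checkerboard-free.

## Synthetic scenes: what they emulate and what they do not

The field dataset behind the method is private, so the package generates
labeled scenes with its statistical structure: 224×224 RGB (configurable),
1–3 corn plants rendered as unions of elongated ellipse lobes around a stem
(characteristic radius 30–60 px), 0–20 weeds rendered as small discs or thin
blades (3–12 px), weed placement inside a corn plant's bounding circle with
probability 0.2 (occlusion pressure), soil as a base tone with coarse
patchiness and fine grain (amplitude 12 on the 0–255 scale), a global
illumination factor drawn from [0.7, 1.3], and overlapping-but-distinct
green hue distributions for the two foreground classes so the task is not
separable by color alone. Occlusion is resolved by paint order (weeds drawn
after corn), keeping image and mask trivially consistent. The class-frequency
defaults are stand-ins — the source imagery's distribution is uncharacterized
— and all of them are exposed in `scene_spec()`.

Passing tests on these scenes demonstrates that the architecture,
optimization and evaluation machinery are correct and that the model can fit
scale-disparate overlapping classes. It does *not* demonstrate field-level
accuracy: real canopies have texture, specularity, shadows, soil residue and
perspective effects the parametric renderer does not attempt
(photorealism is an explicit non-goal). A `corn_shape = "disc"` diagnostic
mode exists purely because a disc's painted area has a closed form (πr²),
which gives the rasterizer an exact geometric oracle.

## Dataset protocol

- **Layout.** Pascal-VOC segmentation: `JPEGImages/<id>.jpg`,
  `SegmentationClass/<id>.png` as indexed-palette PNGs (index 0/1/2 =
  black/green/red, matching the overlay convention), and
  `ImageSets/Segmentation/{train,val,test}.txt`. No installed R package
  writes palette PNGs, so the writer assembles the five PNG chunks directly
  (deflate via `memCompress`, compiled CRC-32); masks are read back through
  `png::readPNG` and mapped palette-color → class index, and any color or
  index outside the palette is a format error.
- **Labelme conversion.** Polygon annotations rasterize in file order with
  an even-odd pixel-center test ("corn" → 1, "grass" → 2; unknown labels are
  format errors). Pixel centers sit at half-integer coordinates, so an
  axis-aligned square polygon from (10,10) to (20,20) covers exactly 100
  pixels.
- **Augmentation.** Four strategies, each applied independently with
  probability 0.5: Gaussian noise (σ = 8 intensity units), rotation (uniform
  ±30° — the protocol fixes no range, so it is configurable), photometric
  adjustment (brightness and contrast factors in [0.8, 1.2], plus global
  histogram equalization of the luminance channel — "histogram" comes with
  no formula, equalization is our reading), and motion blur (7-px line
  kernel at a random angle). Rotation is the only geometric strategy and is
  applied identically to image (bilinear, border filled with the per-image
  median background color) and mask (nearest-neighbour, class-0 fill —
  labels are never interpolated); photometric strategies touch the image
  only.
- **Expansion and splits.** `expand_dataset()` keeps originals and adds
  augmented replicates round-robin over sources until the target count
  (4000 from 500 in the reference protocol). Splitting is 8:2 into
  train+val/test and 8:2 again into train/val (64/16/20% of N). The stated
  order — augment first, then split — risks leaking replicates of one source
  across splits, so the splitter assigns *sources* (with all their
  replicates) to splits; with equal replicate counts per source the split
  sizes still hit round(N·f) exactly (4000 → 2560/640/800).
- **Annotation preprocessing.** The grayscale + contrast-stretch step
  (ITU-R 601 luminance, linear stretch of the occupied range to [0, 255],
  identity on constant images) applies to annotation imagery only; the
  network consumes 3-channel RGB, as the 3-channel 7×7 stem requires. The
  source text is ambiguous here; the annotation-side reading is the one
  consistent with an RGB input layer.

## Training

`train_config()` defaults encode the published protocol: 100 epochs, batch
4, Adam at learning rate 0.001, β₁ = 0.9 ("momentum 0.9" — Adam has no
classical momentum, so β₁ is the defensible reading), weight decay 1e-4
("decay rate", added to gradients as an L2 term), Dice loss, random
initialization (no pretrained weights). "100 iterations" is read as 100
epochs, consistent with how the loss-curve axis is used. The loss is
softmax + multiclass soft Dice, `d_k = (2Σp_k t_k + ε)/(Σp_k + Σt_k + ε)`
with ε = 1e-6, summed over all pixels of the batch and averaged over all
three classes including background (`include_background = FALSE` drops class
0). Images are scaled to [0, 1] and standardized per channel with
constants computed on the training split and frozen into the checkpoint.

Everything is seeded end-to-end (initialization, shuffling, batching), so a
fixed seed reproduces epoch-one losses to machine precision. Checkpointing
keeps `best.rds` (weights, by validation MIoU — or training loss when no
validation split exists) and `last.rds` (weights + Adam moments + RNG state)
for exact resumption; passing a finished `rds_train_result` back to
`train()` continues the same run in memory, which is byte-equivalent to one
longer run and is how long schedules are executed in slices. Non-finite
losses raise a divergence error naming the epoch and step. Learning-rate
schedules, early stopping and mixed precision are out of scope.

## Evaluation

All metrics derive from a 3×3 pixel confusion matrix (rows = truth, columns
= prediction), accumulated associatively over images. MIoU averages
`TP/(TP+FP+FN)` over classes; precision `TP/(TP+FP)` and recall `TP/(TP+FN)`
are macro-averaged over classes by default (the aggregation behind the
printed single numbers is unstated; macro matches the class mean of the IoU
definition, and `average = "foreground_only"` is provided). Classes absent
from both truth and prediction are *excluded* from the mean rather than
scored zero, so images lacking a class do not penalize the score; if no
class is defined the metric raises an undefined-metric error rather than
returning NaN. Mask argmax breaks ties toward the lowest class index.
`measure_fps()` reports single-image wall-clock throughput; it is
hardware-bound and never a correctness quantity. Overlays color corn green
and weeds red over the input, and `render_panel()` writes
image | truth | prediction strips for qualitative review.

## Numerical conventions

- Tensors are dense double arrays `(H, W, C, N)`; convolutions are
  zero-padded cross-correlations; im2col + BLAS GEMM with the batch folded
  into one product.
- Bilinear sampling and the 2× upsampler use half-pixel alignment; the
  upsampler clamps to edges, the deformable sampler treats outside as zero
  (matching zero padding).
- Max-pooling resolves ties to the first element in row-major window order;
  windows are effectively -inf padded.
- Batch-norm uses ε = 1e-5, biased variance, and running moments with
  momentum 0.1 for evaluation mode.
- Adam uses ε = 1e-8 with bias correction; the update is compiled and
  in-place, so parameter and moment arrays are never copied.
- Gradients of every operator (convolution, deformable convolution with
  respect to input/weights/offsets, pooling, upsampling, normalization,
  gates, Dice) are validated against central finite differences in the test
  suite.

## Problem sizes used by the checks

The automated checks run at sizes chosen to exercise every code path on a
single CPU: geometric and operator oracles at 4–8 px feature maps; the
dataset-protocol check generates 500 scenes at 32 px and expands to 4000;
the learning smoke check trains the full model on eight 64-px scenes until
training MIoU exceeds 0.90 (within 300 optimization steps, two seeds); the
ablation trend check compares plain and full variants on thirty 32-px
scenes over three seeds at four epochs and asks only for the median
direction, not magnitudes. The acceptance script trains the full model for
eight epochs on forty 64-px scenes. These are deliberate desk-scale
choices: they demonstrate correctness and direction, and full-scale numbers
require real field data and a long 224-px training run.

## Known limitations

- The synthetic scenes bound what the green-field metrics mean (see above);
  no claim transfers to real imagery without retraining.
- Double-precision CPU kernels favor exactness and testability over
  throughput; FPS numbers are not comparable to GPU deployments.
- Batch normalization with batch size 4 has noisy statistics at very small
  training-set sizes; the running-moment momentum (0.1) assumes at least a
  few dozen steps before evaluation-mode statistics are trustworthy.
- Modulated (v2) deformable convolution, deformable RoI pooling, and the
  comparison baselines from the broader literature (PSPNet, DeepLabV3) are
  out of scope.
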