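---
title: "Cascaded Self-ONN segmentation: models, choices, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascaded Self-ONN segmentation: models, choices, and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Liver tumors on contrast-enhanced abdominal CT are small, variable in
shape, and close in attenuation to surrounding liver tissue.  A common
and effective strategy is a *cascade*: one encoder–decoder network
segments the liver on each axial slice, the resulting binary mask is
placed over the slice to form a liver region of interest (ROI), and a
second network searches for tumor only inside that ROI.  `sonnseg`
implements this cascade with decoders built from *self-organized
operational neural network* (Self-ONN) layers, alongside plain U-Net,
nested U-Net (U-Net++) and feature-pyramid (FPN) decoders over
ResNet/DenseNet encoder backbones.

## The generative neuron

A convolutional neuron computes a weighted sum of its inputs — a linear
nodal operator.  A generative neuron instead learns its nodal operator
as a truncated MacLaurin series: for a scalar input $x$,

$$f(x) = c + v_1 x + v_2 x^2 + \dots + v_q x^q,$$

where each $v_k$ is a full spatial kernel and $c$ a per-output-channel
bias.  A Self-ONN layer therefore applies a separate kernel to each
integer power of its input and sums the results:

$$y_o(p) = c_o + \sum_{k=1}^{q} \sum_{i} \sum_{u,v}
  w^{(k)}_{o,i,u,v}\, x_i(p + (u,v))^k .$$

The pool operator is summation; out-of-support positions contribute
zero (zero padding).  Setting $q = 1$ recovers an ordinary
cross-correlation, which the tests exploit as an exact equivalence
check.  The derivatives of the underlying function are absorbed into
the learned $v_k$ and never represented explicitly, and the series has
no learned expansion point (MacLaurin form, $b_0 = 0$).

Two practical consequences drive several design choices:

* **Input range.**  Powers of magnitudes above 1 explode.  Every
  Self-ONN layer in this package expects inputs in $[-1, 1]$: images are
  mapped from $[0, 255]$ to $[-1, 1]$ before entering a Self-ONN model
  (`scale_for_model(style = "selfonn")`), and every Self-ONN layer is
  followed by `tanh`, which both adds the non-linearity the original
  formulation uses and guarantees the next layer's input range.
* **No extra normalisation.**  Plain convolution decoder units use
  batch normalisation (bias-free convolution + BN + ReLU, the standard
  arrangement); Self-ONN units use none, because `tanh` already bounds
  their activations and per-power kernels see a bounded domain.

**Initialisation.**  Per-power kernels are drawn uniformly from
$[-a, a]$ with $a = 1/\sqrt{\text{fan\_in} \cdot q}$.  This is the
variance-scaled choice: with inputs bounded by 1, the sum over
`fan_in * q` terms keeps unit-scale pre-activations regardless of the
Taylor order.  All randomness flows through explicit seed arguments.

## Residual blocks

Two composite units follow the block descriptions used at the
bottleneck of the architecture:

* `selfonn_resblock`: 3×3 Self-ONN → tanh → 1×1 Self-ONN restoring the
  input channel count → tanh → residual addition with the input.  With
  all weights and biases zero the block is exactly the identity.
* `selfonn_conv_resblock`: a Self-ONN path (3×3 then 1×1, each with
  tanh) in parallel with a plain 3×3 convolution path, combined
  elementwise.

The textual description of these blocks mixes spatial and channel
dimensions ("$n \times n$ input, $4n \times 4n$ output"); a literal
spatial 4× expansion could not be summed with an $n \times n$ residual,
so this package reads the factors as *channel* expansion (and
"$n/4$" as channel reduction), the only interpretation under which the
described residual additions are well-formed.  The combination of the
two parallel paths is elementwise addition by default — it preserves
the stated output size, while a channel-concatenation variant remains
available behind `combine = "concat"`.

## Architectures

Encoders are faithful re-implementations of the ResNet (18/50/101/152)
and DenseNet (121/161/201) classifiers with the classifier heads
removed, exposing feature maps at strides 2–32; their parameter counts
match the standard reference implementations exactly (11,176,512 for
the ResNet18 extractor, 18,092,928 for DenseNet201).  ImageNet weights
can be loaded from a local file; nothing is ever downloaded, and no
test requires pretrained weights.  A `tiny` family (< 100k parameters)
exists so end-to-end behaviour can be exercised quickly on a CPU.

Decoders: `unet` (five upsampling blocks, each concatenating the
matching encoder skip and applying two convolution units), `unetpp`
(nested dense skip grid), `fpn` (lateral 1×1 projections, top-down
pathway, per-level maps merged on the stride-4 grid and 3×3-convolved),
and `selfonn_unet` — the U-Net topology with every decoder convolution
unit replaced by a Self-ONN layer + tanh.  The head is a 1×1
convolution to two channels (3×3 for FPN) followed by a channelwise
SoftMax; foreground is channel 2, and argmax ties resolve to
background, the conservative choice for lesion calling.

Whether the original design placed Self-ONN blocks only at the
bottleneck or throughout the decoder is described inconsistently in the
source material; the default here is Self-ONN throughout the decoder,
with `selfonn_bottleneck_only = TRUE` available.

## The reference configurations and the calibration search

The published complexity analysis reports 20,622,065 trainable
parameters for the ResNet18-encoder Self-ONN U-Net and 49,546,289 for
the DenseNet201 variant.  With the default halving decoder widths
256/128/64/32/16 and $q = 3$, both counts come out exactly 4,177 high —
while the *difference* between the two published counts matches this
structure exactly, which pins the encoder families, the product of
Taylor order and deep decoder widths, the skip wiring and the kernel
sizes.  The residual constant is some unpublished width detail of the
original decoder.

`calibrate_decoder_channels()` performs the documented calibration: the
difference constraint fixes $q(2944 d_1 + 384 d_2 + 192 d_3)$, so the
search enumerates integer $(d_1, d_2, d_3)$ on that surface and solves
a quadratic for $(d_4, d_5)$.  Among the exact joint solutions, the one
closest to the default widths under the canonical remaining choices
($q = 3$, biased layers, biased 1×1 two-channel head, 3-channel input)
is decoder channels **256/124/72/25/33**.  That configuration is
recorded as `reference_selfonn_unet_spec(calibrated = TRUE)` and
reproduces both published counts; the default halving widths remain the
package default for actual training work.

## Preprocessing

CT volumes arrive in Hounsfield units.  `hu_window()` clips to
$[-100, 400]$ (the liver window), `rescale_to_255()` maps linearly to
$[0, 255]$ (real-valued by default; an optional `uint8` mode rounds
half away from zero), and `volume_to_slices()` extracts axial slices
(third array axis, 0-based indices, the LiTS convention) with
`liver_mask` = labels ∈ {1, 2} and `tumor_mask` = label 2 — tumor
voxels are liver tissue.  Slices without liver are dropped by default
for liver-model training, with an explicit `keep_empty` flag, since the
original slice-inclusion policy is unstated.  The loader takes explicit
file lists and imposes no train/test split: the published description
of the LiTS split inverts the usual 131/70 convention, so no split is
hard-coded.

## The phantom generator

Real LiTS data cannot be redistributed and is far too large for
routine testing, so `generate_phantom_volume()` emulates its structure:
one smooth elliptical liver-like region whose centre and axes vary
smoothly over a consecutive run of axial slices; zero to three
hypodense tumor balls strictly inside the liver (anisotropic in z to
respect the 2.5 mm slice spacing); liver tissue at 50–70 HU, tumors at
10–40 HU, background at −80 HU; additive Gaussian noise of 8 HU on the
image and noiseless labels.  Everything is determined by
`(seed, volume_index)`.

These values make the phantoms *deliberately easy*: contrast is high,
shapes are smooth and convex, there are no neighbouring organs,
streak artifacts, or ambiguous boundaries.  Passing the end-to-end
tests therefore demonstrates that the layers, gradients, cascade
plumbing, training loop and metrics work — it says nothing about
clinical difficulty or expected performance on real CT, where the
published experiments required the full LiTS dataset and GPU-scale
training.

## Training protocol

`train_config()` defaults follow the published training table: Adam
(betas 0.9/0.999), learning rate 1e-4, batch size 8, at most 50
epochs, early stopping after 10 epochs without validation improvement,
learning-rate drop by factor 0.2 after 6 plateau epochs, soft dice
loss.  Where the prose and the table disagree (1e-3 vs 1e-4, batch 16
vs 8, 40 vs 50 epochs, patience 5 vs 6/10), the structured table wins;
every value stays configurable.

The dice loss is the squared-denominator form
$D = 2\sum p_i g_i / (\sum p_i^2 + \sum g_i^2)$ on the foreground
probability channel, with $0/0$ defined as 1 (an empty prediction of an
empty reference is perfect — the convention that also makes zero-dice
counting meaningful, since a missed structure scores 0, not undefined).
Its analytic gradient is verified against finite differences.

Cross-validation splits are made *by volume*, never by slice, so no
volume's slices leak across train/validation/test; ~20% of volumes form
each rotating test block and the last 20% (floor) of the remaining
block becomes validation.  "Best model" means the lowest-validation-
loss checkpoint, whose weights (and batch-norm running statistics) are
returned.  One behavioural note: batch-norm running statistics evolve
during training even when the learning rate is zero, so a zero-lr run
of a batch-normalised model can still show (genuine) validation
improvement; the stopping-rule tests use a normalisation-free model so
that only the optimizer state matters.

For the tumor stage, training inputs are ROIs built from *ground
truth* liver masks, while evaluation always runs the full cascade with
*predicted* stage-1 masks.  The ROI is the elementwise product of image
and mask by default (the mask "placed over" the image; a two-channel
concat mode exists), and `constrain_tumor_to_liver` is off by default
since no post-hoc intersection is described; no inter-stage
post-processing (largest component, hole filling) is applied.

## Problem sizes used by the test suite

The end-to-end demonstration (`tiny_cascade_experiment()`) uses five
64×64 phantom volumes of 12 slices (three for training, one for
validation, one held out), a tiny encoder with a Self-ONN decoder of
widths 24/16/12/8/8 at $q = 3$, at most 200 Adam steps per stage at
learning rate 1e-3 (the conventional from-scratch rate for such small
networks; the 1e-4 default is tuned for the full-size transfer-learning
setting), batch size 4.  Under these conditions stage 1 typically
reaches a held-out liver DSC above 0.99 and the full cascade a tumor
DSC around 0.7–0.9; the suite requires liver ≥ 0.90 and tumor ≥ 0.60
in at least two of three seeds.  These sizes were chosen so the whole
experiment runs in minutes on one CPU core.

## Numerical implementation notes

All tensor work is plain R: convolutions are an im2col gather followed
by one BLAS matrix product, with the gather/scatter index sets cached
as sparse matrices so the backward pass is a single sparse product;
bilinear 2× resampling is a pair of precomputed interpolation-matrix
products (half-pixel-centre convention); networks are small explicit
DAGs with reverse-mode gradient accumulation.  A deliberately naive
nested-loop implementation of the Self-ONN forward pass
(`selfonn_forward_bruteforce`) serves as the independent oracle the
vectorised path is tested against, and every layer's analytic gradient
is checked against central finite differences.

## Known limitations

* No 3-D convolutions; the cascade is strictly slice-by-slice, and
  volume masks are reassembled from per-slice predictions.
* No surface-distance metrics (HD95/ASSD) and no volume-level dice
  aggregation beyond per-slice reporting; confidence intervals are
  normal-theory half-widths over pooled test slices.
* ImageNet pretraining is supported only via locally provided weight
  files.
* The phantom generator emulates geometry and contrast, not clinical
  appearance; results on phantoms do not transfer to real CT.
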