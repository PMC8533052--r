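---
title: "MF-Net and SemiMF-Net: model, design choices and numerical notes"
author: "MFNet package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MF-Net and SemiMF-Net: model, design choices and numerical notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The segmentation problem

Choroidal neovascularization (CNV) appears in retinal OCT B-scans as an
irregular hyperreflective region disrupting the layered retinal bands.
Three properties make automatic segmentation hard: the lesion boundary
is blurred, lesion morphology varies enormously between eyes, and OCT
images carry strong multiplicative speckle noise. MF-Net addresses the
first two with explicit multi-scale machinery; robustness to speckle
comes from learning on speckled data.

## Architecture

The backbone is a four-stage encoder--decoder *without* same-level skip
connections. Each encoder stage is two (3x3 convolution, batch norm,
ReLU) blocks followed by 2x2 max pooling; channel widths double per
stage from `baseChannels` (64 by default, so 64/128/256/512). Each of
the three decoder stages is a bilinear x2 upsample followed by one
(3x3 convolution, batch norm, ReLU) block; a head restores the final
x2 to input resolution and maps to a single sigmoid channel. Two
modules are grafted onto this skeleton:

**MAD (multi-scale adaptive-aware deformation)**, inserted after
Encoder 4, has four parts:

1. *Parallel dilated branches.* Four 1x1 convolutions squeeze the
   `c` input channels to `c/4` each; 3x3 convolutions with dilation
   rates 1, 3, 5, 7 (branch `k` uses rate `2k - 1`) enlarge the
   receptive field at four scales; the outputs are concatenated back to
   `c` channels.
2. *Deformable fusion.* One 3x3 deformable convolution whose 18
   per-position offset channels (a 2-D displacement per kernel tap) are
   predicted by an auxiliary 3x3 convolution on the same input, so the
   sampling grid adapts to lesion deformation. Sampling is bilinear
   with zero padding outside the map.
3. *Dual global attention.* A spatial map
   `S = sigmoid(conv7x7([max_c B; mean_c B]))` (one channel, values in
   (0,1)) and a channel vector
   `C = sigmoid(FC(conv1x1([maxpool B; avgpool B])))` (length `c`).
4. *Adaptive residual.*
   `O = B + conv3x3(lambda * (B (x)_s S) + gamma * (B (x)_c C))`, where
   the two broadcasts multiply spatially and channel-wise and the
   scalars `lambda`, `gamma` are learnable, initialized to 1.

**SDA (semantics--details aggregation)** replaces the two shallow skip
connections: `S^k = conv3x3(up2(F^k)) * E + D`, where `F^1` is the
Decoder 3 output and `F^2` the first SDA output, `E` the stage's
encoder detail map and `D` its decoder map. Upsampled deep semantics
gate the high-resolution encoder detail multiplicatively before it is
added to the decoder stream, suppressing clutter that plain skips would
inject. No skip exists from Encoder 3 or 4. There is deliberately no
normalization or activation inside SDA, which keeps its algebra exactly
testable (zero gate returns `D`; unit gate returns `E + D`).

## Training objective

For probabilities `X` and binary target `Y`,

* Dice loss: `1 - (2*sum(XY) + eps) / (sum(X) + sum(Y) + eps)` with
  `eps = 1e-6` (the smoothing defines the empty-mask case); for a batch
  the per-sample Dice losses are averaged.
* BCE: mean over pixels of `-(Y log X + (1-Y) log(1-X))`, probabilities
  clamped to `[1e-7, 1 - 1e-7]`. We use the *mean* rather than a pixel
  sum so that the two components stay on comparable scales regardless
  of image size.
* Joint loss: their exact, unweighted sum.

Optimization is Adam (lr 5e-4, weight decay 1e-4, batch 4, 50 epochs by
default). Gradients flow through a hand-written backward pass for every
layer; the BCE gradient is fused with the head sigmoid for numerical
stability.

## SemiMF-Net

Three steps: (1) pre-train MF-Net on the labeled set; (2) run the model
over the unlabeled images and binarize at 0.5 to obtain pseudo-labels
(no confidence filtering); (3) re-train on the pooled set under
`L_pseudo + beta * L_real` with `beta = 1` by default. Within a pooled
batch each sample contributes its joint loss with weight 1
(pseudo-labeled) or `beta` (real-labeled), normalized by the batch
size; with `beta = 1` this is exactly the uniform mean joint loss over
the batch, which the test suite asserts. Retraining warm-starts from
the pre-trained weights (a `warmStart = FALSE` flag re-initializes);
only one pseudo-labeling round is performed and mixed batches are drawn
without provenance balancing.

## Evaluation

Probability maps are binarized at 0.5 (fixed; only pseudo-labeling
exposes its own threshold) and scored per image as percentages:
`DSC = 2TP/(FP + 2TP + FN)`, `SEN = TP/(TP + FN)`,
`JSC = TP/(FP + TP + FN)`. When a denominator is zero the metric is 100
if both masks are empty and 0 otherwise. Cross-validation uses the
fold scheme "floor(N/k) ids for folds 1..k-1, remainder in fold k"
after a seeded shuffle — the unique scheme that reproduces the
published split of 1,522 scans into folds of 380/380/380/382. Method
comparisons across folds use a two-sided paired t-test
(`pairedTTest()`), with the conventions p = 1 for identically zero
differences and the smallest positive double for zero-variance nonzero
differences.

## The synthetic benchmark

`synthBscan()` emulates exactly the features the method targets:
curved, layered hyperreflective bands (retina), one simply connected
star-convex lesion with a Fourier-perturbed radius (large morphological
variability), a Gaussian-blurred lesion boundary (sigma 1.5 px by
default, mimicking the indistinct CNV margin) and multiplicative
gamma-distributed speckle with mean 1 (variance 0.08 by default, the
standard multiplicative model for coherent imaging). The lesion is
brighter (0.88) than every band (at most 0.55), so in the noiseless,
unblurred limit it is the unique brightest region; the ground-truth
mask is the exact pre-blur polygon raster. Lesion area is
rejection-sampled into 3--12% of the image. Every sample is a pure
function of its seed.

What the generator does *not* emulate: other pathologies (fluid
pockets, drusen), vessel shadowing, acquisition artifacts, anatomical
correlation between neighboring B-scans, and realistic intensity
calibration. Passing the synthetic benchmark therefore demonstrates
that the implementation can learn a speckled, blurred-boundary,
shape-variable segmentation task end to end — not clinical-grade CNV
performance, which requires the real annotated dataset and full-scale
training.

## Numerical choices

* Layer layout is `(h, w, c, n)` double arrays at the R boundary; the
  heavy convolution GEMMs run in single precision via im2col +
  OpenBLAS, which is the usual precision for network training. All
  reductions accumulate in double. An option
  (`MFNet.conv.double = TRUE`) switches the GEMMs to double precision;
  the gradient-check tests use it so numeric differentiation is not
  limited by float32 forward noise.
* Batch norm uses biased batch variance for normalization, unbiased for
  the running estimate (momentum 0.1, eps 1e-5); evaluation mode uses
  running statistics.
* Bilinear x2 upsampling uses the half-pixel (align-corners-false)
  convention; its backward pass is the exact adjoint, which the tests
  assert via the inner-product identity.
* The deformable convolution's offset predictor is zero-initialized, so
  at initialization the layer is exactly a standard 3x3 convolution
  (asserted to 1e-5). At integer sampling positions bilinear
  interpolation is only one-sidedly differentiable; the backward pass
  uses the right-derivative convention, as standard implementations do.
* Max-pool and channel-max attention break ties by first index.
* He-normal weight initialization; all biases start at zero;
  `lambda = gamma = 1`.

## Scale of the shipped experiments

The test suite and the acceptance script run a reduced configuration
chosen to exercise every component at workstation scale: base 16
channels, 128x128 inputs, 200/50 train/test images for the supervised
benchmark (15 epochs, seed 0) and 50 labeled + 100 unlabeled for the
semi-supervised smoke run. Under these conditions the trained reduced
MF-Net must reach a held-out mean DSC of at least 80 and beat an Otsu
thresholding baseline by at least 10 points, and the semi-supervised
model must stay within 2 DSC points of its supervised pre-training.
These margins are contracts on the implementation, not claims about the
full-scale clinical task.

## Known limitations

* CPU-only; full-scale training (hundreds of 256x256 scans, 50 epochs,
  base 64) is possible but slow.
* The encoder trains from scratch; no pretrained weights are bundled
  (the constructor is deterministic given the RNG state, so seeded
  retraining is the reproducible path).
* No data augmentation or learning-rate schedule by default; both can
  be layered on top of `trainSupervised()` by transforming the sample
  list.
* Single-lesion, binary segmentation only.
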