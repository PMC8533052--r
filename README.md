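# MFNet

Segmentation of choroidal neovascularization (CNV) lesions in retinal
OCT B-scans with **MF-Net**, a multi-scale information-fusion
encoder–decoder network, and its pseudo-label semi-supervised variant
**SemiMF-Net**. The package is a complete, CPU-only R implementation:
every layer (dilated and deformable convolution, batch normalization,
max pooling, bilinear upsampling) ships with a hand-written backward
pass in C++, trained by Adam on a joint Dice + binary-cross-entropy
objective. A seeded generator of OCT-like synthetic B-scans makes the
whole pipeline runnable and testable without any external dataset.

## The model

The backbone is a four-stage encoder–decoder *without* same-level skip
connections. Two modules are added:

- **MAD** (multi-scale adaptive-aware deformation), after Encoder 4:
  four parallel dilated branches (1×1 squeeze to c/4, then 3×3
  convolutions at dilation rates 1/3/5/7) are concatenated and fused by
  a 3×3 deformable convolution with learned per-position sampling
  offsets, giving B. Dual global attention
  S = σ(conv₇ₓ₇([max_c B; mean_c B])) (spatial) and
  C = σ(FC(conv₁ₓ₁([maxpool B; avgpool B]))) (channel) feed an adaptive
  residual

  O = B ⊕ conv₃ₓ₃(λ·(B ⊗ₛ S) ⊕ γ·(B ⊗_c C)),  λ, γ learnable, init 1.

- **SDA** (semantics–details aggregation), replacing the two shallow
  skips: Sᵏ = conv₃ₓ₃(up₂(Fᵏ)) ⊗ E ⊕ D — upsampled deep semantics
  multiplicatively gate encoder detail before addition to the decoder
  stream. No skip from Encoder 3/4.

Training: L = L_Dice + L_BCE, Adam (lr 5e-4, weight decay 1e-4,
batch 4). SemiMF-Net: pre-train on labeled data, pseudo-label the
unlabeled pool at threshold 0.5, re-train on the mixed set under
L_Pseudo + β·L_Real (β = 1). Evaluation: DSC = 2TP/(FP+2TP+FN),
SEN = TP/(TP+FN), JSC = TP/(FP+TP+FN) in percent, 4-fold
cross-validation, paired t-tests across folds.

## Worked example

```r
library(MFNet)

# synthetic OCT-like data: layered bands + one bright irregular lesion
train <- synthSamples(200, synthParams(imageSize = c(128, 128), seed = 0))
test  <- synthSamples(50,  synthParams(imageSize = c(128, 128), seed = 10000))

cfg <- trainConfig(epochs = 15, seed = 0,
                   network = mfNetConfig(baseChannels = 16,
                                         inputSize = c(128, 128)))
fit <- trainSupervised(cfg, train, verbose = TRUE)
#> epoch 1: train loss 0.2424
#> ...
#> epoch 15: train loss 0.0420

evaluateModel(fit$model, test)
#> MetricsReport (50 images):
#>   DSC   97.12 +/- 0.70
#>   SEN   97.30 +/- 1.14
#>   JSC   94.40 +/- 1.32

otsuBaseline(test)@mean[["DSC"]]
#> [1] 39.65932
```

The trained reduced network reaches a held-out Dice of ~97% on the
synthetic benchmark; the Otsu thresholding baseline stalls near 40%
because the retinal bands are also hyperreflective — the network has
to learn shape and context, not just brightness. `mfNetForward()`
returns the probability map for a single image; `renderOverlay()`
draws the yellow (correct) / red (false positive) / blue (false
negative) comparison image; `crossValidate()` and `pairedTTest()`
reproduce the fold-level evaluation protocol (1,522 ids split 4-fold
as 380/380/380/382).

A thin CLI over the same functions lives at `inst/scripts/mfnet`
(subcommands `synth`, `train`, `cross-validate`, `predict`,
`evaluate`, `pseudo-label`, `train-semi`).

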