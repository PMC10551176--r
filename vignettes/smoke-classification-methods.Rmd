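---
title: "Methods: re-parameterized convolutional Poolformer for surgical smoke detection"
author: "endosmoke authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: re-parameterized convolutional Poolformer for surgical smoke detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endosmoke)
```

## The problem

Electro-cautery produces intermittent smoke during endoscopic surgery.
Desmoking algorithms that enhance every frame of the video stream waste
computation on the (majority) smoke-free frames and can degrade them. A fast
binary classifier — *does this frame contain smoke?* — lets the desmoking
stage run only where it helps. The operating constraints are unusual:
endoscopic tissue is non-Lambertian and weakly textured, so local detail
matters more than in natural images, and the gate must run at video rate.

endosmoke implements such a classifier and everything needed to exercise it
end to end without external data: a procedural synthesizer of labeled
smoke / smoke-free endoscopic-style frames, the model itself, a structural
re-parameterization that converts the trained multi-branch network into a
single-path inference network, and a training/evaluation pipeline.

## Model

The model follows the MetaFormer template: a tokenizer turns the image into
a sequence of spatial tokens, a stack of `L` blocks alternates token mixing
with channel MLPs inside residual branches, and a head pools the sequence
into one feature vector for a linear classifier.

**Convolutional tokenizer.** Instead of large-stride patch embedding (a
16×16/stride-16 convolution in ViT-B/16), the stem is a small convolutional
pipeline — conv3×3/s2 → GELU → maxpool3×3/s2 → ResNet-style residual block →
conv3×3/s2 → flatten — so neighbouring patches share intermediate
computation and fine detail survives. Total stride is 8 by default (a
stride-16, 768-channel preset reproduces the ViT-compatible 197×768 token
layout, class token included). The GELU is the exact `x·pnorm(x)` form. Stem
convolutions use replicate padding, so a spatially constant field maps to
identical tokens. A learnable, zero-initialized positional table is added to
the tokens. The token count is a pure function of input size and stride;
any input at least as large as the total stride tokenizes.

**Token mixer.** Pooling (the Poolformer choice) is cheap but lossy on
weakly textured inputs. Here the mixer is a multi-branch depthwise
convolutional block in the ConvNeXt family: parallel depthwise convolutions
at 7×7 and 3×3, each followed by its own batch normalization, plus an
identity branch. The identity branch *is* the token-mixing residual; the
per-branch batch norms realize pre-norm placement inside the branch. The
channel MLP (layer norm → expand ×4 → GELU → project) sits in a second
residual. Token mixing is therefore depthwise-only — all cross-channel
mixing lives in the MLP, matching both pooling (channel-independent) and
the ConvNeXt depthwise stage. With all mixer and MLP weights zero the whole
encoder is the identity map, which the tests assert.

One design point deserves a note: a formulation that wraps an *extra*
residual around a mixer that already contains an identity branch would
double the skip path (`x + (x + conv(x))`). The package therefore treats
the mixer's identity branch as the only skip of the mixing stage. This is
the RepVGG-style family that the single-path conversion below requires, and
it preserves all identity limits (zero kernels with identity normalization
give an exact identity block).

**Head.** No class token is sliced in the default path. A learned scalar
score per token is softmax-normalized over the sequence and used to average
the tokens (sequence pooling); a single linear layer maps the pooled
feature to the two logits. An optional one-hidden-layer head is available
behind a configuration flag, but the default follows the more specific
"linear classifier" reading.

## Structural re-parameterization

At inference each branch's batch normalization is an affine map with frozen
statistics, so it folds into the convolution:
`k' = k·γ/√(σ²+ε)`, `b' = β − μ·γ/√(σ²+ε)`. Folded kernels are zero-padded
to the largest branch size (7×7), the identity branch becomes a centred
Dirac kernel, and everything sums into one depthwise convolution plus bias.
The fused network computes the same function: the package asserts
`≤ 1e-5` agreement at block level and `≤ 1e-4` on whole-model logits
(comfortably met in double precision), exact label agreement, and `≤ 1e-10`
agreement with an independent brute-force direct-summation convolution.
Fusing an already-fused block is the identity, and deployment refuses
unfrozen statistics or double fusion. Batch normalization uses the biased
(population) variance in both normalization and the running moments so that
the fold is exact.

The single-path network does strictly less work (one depthwise convolution
instead of two plus two normalizations per block) and carries strictly
fewer mixer parameters; the multi-branch capacity is paid only at training
time. The memory argument — the residual topology holds roughly two
activations alive where the plain topology holds one — is documented here
but not asserted by tests, since it is allocator-dependent.

## Synthetic data

The generator stands in for real laparoscopic frames augmented with
physically rendered smoke; it is a procedural emulation, not a
reproduction, of such data.

*Base frames* are low-texture, red-dominant fields: multi-octave value
noise drives the red/green channels, a radial vignette darkens the
periphery of the light cone, and 0–3 Gaussian specular blobs mimic
wet-tissue highlights. The red-channel mean always exceeds the blue.

*Smoke* is a multi-octave fractal noise field modulated by an elliptical
Gaussian envelope centred at the plume position. Intensity (in [0,1])
scales the added luminance linearly, so the layer peak is strictly monotone
in it; density (in [0,1]) scales the envelope radii linearly
(`R = (0.08 + 0.42·d)·size`, capped below the frame size so the support
fraction stays strictly monotone instead of saturating); the envelope is
truncated below 0.05 so the layer has finite support and exact zeros
outside it. The layer is a scalar (luminance) field added equally to all
three channels and clipped at 255 — pure addition with sensor saturation,
never rescaling — so clean pixels outside the support stay bit-identical.

*Datasets.* The full-scale configuration writes 5,000 frames of 384×192,
one fifth smoke-composited, stratified into 3,800 train / 1,200 test with
an exact 4:1 smoke-free:smoke ratio in each split. Builds are byte-for-byte
reproducible from the master seed (labels, splits, per-image parameters and
per-image noise seeds are all derived from it). Configurations whose
(label × split) cells are not integers are rejected. Smoke parameters are
sampled uniformly from intensity ∈ [0.3, 1] and density ∈ [0.3, 0.9]; the
distributions behind the original rendered data are not published, so these
ranges are declared choices, set once so that every smoke-labeled frame is
visibly smoky and the tiny-scale task is learnable.

What the generator does *not* emulate: photorealistic scattering, video
temporal coherence, instrument clutter, specular saturation of real
endoscopes. Passing tests therefore demonstrate that the pipeline is
correct and that the model can learn the additive-haze cue, not that it
reaches any particular accuracy on real surgical video.

## Training and evaluation protocol

Defaults follow the full-scale protocol: inputs bilinearly resized to
224×224, initial learning rate 0.001 with exponential per-epoch decay,
50 epochs, encoder depth `L = 10`, random horizontal flips, 10-fold
stratified cross-validation. The decay factor is not pinned by the
protocol; the package defaults to 0.9 per epoch. The optimizer is likewise
unspecified upstream; AdamW (decoupled weight decay 0.01 on weights only)
is the package default as the standard choice for transformer-family
models, with batch size 32. Cross-validation is used for model selection
and variance reporting; the final reported model is trained on the full
training split. All randomness (fold assignment, initialization, shuffling,
augmentation) derives from one seed, and fold assignments are exactly
reproducible.

Evaluation accumulates the confusion counts with **smoke as the positive
class**: `Acc = (TP+TN)/(TP+FN+FP+TN)`, `Sens = TP/(TP+FN)`. Sensitivity is
reported as NaN with a warning when no positive images are evaluated.
Reported rates are always recomputed from the stored counts, evaluation is
invariant to image order and batch size, and the fused topology produces
identical counts to the training topology. Throughput (images/second,
median of repeated timed passes after a warm-up) is informational only.

## Problem sizes used by the test suite

The package's own verification runs at desk scale, chosen once as the
smallest sizes at which every contract is meaningful: the full-scale
dataset build (5,000 × 384×192) is exercised for its exact counts; the
learnability check trains a depth-2, width-64 model on 64×64 frames
(400 train / 100 test, the same 4:1 stratification) for 10 epochs and
expects test accuracy ≥ 0.95 in at least 4 of 5 seeds; fusion equivalence
uses 20 random block instantiations at widths 4/16/64 and a depth-2 model.
Full-scale training (224×224, L = 10, 50 epochs, 10 folds) is available
through the same functions but is not part of the routine suite.

## Numerical choices and degenerate inputs

* Double precision throughout (R numerics); fusion tolerances stated for
  float32 are met with orders of magnitude to spare.
* Batch norm: momentum 0.1, ε = 1e-5, biased variance (exact fold).
  Layer norm: ε = 1e-6.
* Softmax is computed with max-subtraction; cross-entropy clamps
  probabilities at 1e-12.
* Ties in the argmax label resolve to the first class ("smoke").
* Degenerate inputs are rejected with explanatory errors: frames smaller
  than 32 px, images smaller than the stem stride, plume centres outside
  the frame, non-integer dataset cells, empty token sequences, empty
  evaluation splits, fold/batch mismatches, non-positive folded variances,
  deployment with unfrozen statistics, double fusion.

## Known limitations

* The synthesizer's additive luminance model makes smoke-labeled frames
  brighter on average; a model could pass the tiny-scale check by
  brightness alone. That is inherent to the additive compositing rule, not
  a test artifact.
* Single-resolution encoder: all `L` blocks run at one token resolution
  (no pyramid stages), the reading consistent with a fixed `L` and a single
  positional table.
* Positional embeddings are not interpolated across input sizes: one
  trained model serves one input size.
* The class-token convention is supported for the ViT-compatible preset
  only; the default path never slices a class token.
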