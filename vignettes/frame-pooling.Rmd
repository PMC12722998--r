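---
title: "Frame pooling for ultrasound sweep classification: model and methods"
author: "sonopool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frame pooling for ultrasound sweep classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonopool)
```

## The problem

Point-of-care ultrasound of the abdomen (FAST-style exams of the pelvic/BLD
and right-upper-quadrant/RUQ sites) is used to triage internal bleeding: free
fluid appears as an anechoic (dark) collection next to an organ. A sweep is
captured as a 30-second video at 30 frames per second, and a clinician reads
the *video*, not a single frame — the fluid pocket is only in view for part
of the sweep, at certain probe angles. A classifier trained on individual
frames therefore faces severe label noise: most frames of a positive video
carry no visible cue, yet inherit the video's positive label.

Frame pooling addresses this by stacking $n$ consecutive grayscale frames as
the *channel* dimension of a single convolutional-network input. One
prediction then integrates many probe angles. Windows of $n$ frames are taken
at stride $s$ across the video (with end padding so every window has exactly
$n$ frames), each window receives a softmax confidence pair
$(p_\text{neg}, p_\text{pos})$, the per-video score is the arithmetic mean of
$p_\text{pos}$ over windows, and the video is called positive when the score
reaches a confidence threshold $\tau$ (ties go to positive):

$$\hat{y}(v) \;=\; \mathbf{1}\!\left[\frac{1}{K}\sum_{k=1}^{K}
  p_\text{pos}(w_k) \;\ge\; \tau\right].$$

The reference recipe trains on $n$-frame windows at a 15-frame stride and, at
evaluation time, pools 150-channel windows at 30-s strides (one window per
30-s clip). The operating threshold is identified by sweeping candidate
confidences and taking the best balance of metrics (F1 by default here;
Youden's J and accuracy are available), and two models are compared on the
same videos with an exact McNemar test on their discordant correct/incorrect
counts.

## Windowing semantics

Frame indices are 0-based and windows are half-open $[start, start+n)$.
Start indices are every multiple of $s$ below $T$, giving $\lceil T/s\rceil$
windows, so every frame belongs to at least one window whenever $s \le n$.
Windows running past the last frame repeat the final frame; repeating (rather
than zero-filling) preserves intensity statistics, since a block of zeros
would itself look like an anechoic — i.e. fluid-like — signal. Trailing
windows that are mostly padding are kept, not dropped; with the 30-s capture
recipe this gives 60 training windows per 900-frame video, of which the last
9 are padded. A video shorter than $n$ yields a single, heavily padded
window.

## The backbone and channel patching

The supported backbone, `tiny_cnn`, is a compact three-block network
(3×3 convolutions with 8/16/32 filters, each followed by ReLU and 2×2
average pooling, then global average pooling and a two-logit head) sized so
that the full pipeline trains on an ordinary CPU in minutes. Inputs are
resampled to 32×32 by default and centered from $[0,1]$ to $[-1,1]$ at the
network entry; without centering, optimization on all-positive intensities
takes off unreliably. Weights are drawn by Kaiming initialization
($\sigma = \sqrt{2/\mathrm{fan_{in}}}$, zero biases) under the run seed.

Adapting a backbone to $n$-channel pooled input only requires patching the
first convolution. `patchFirstConv()` implements the kernel-inflation rule:
for each output filter, the mean of its source-channel kernels is replicated
across all $n$ channels and scaled by $c/n$ (source channel count over new
channel count). Two properties follow by linearity of convolution: the
response to a channel-constant stack equals the source response to the
corresponding gray input (tested to 1e-5), and the expected first-layer
activation magnitude is preserved. When the source is a trained single-frame
model, the inflated first layer computes exactly the temporal average of the
learned frame features — a $\sqrt{n}$ reduction of uncorrelated speckle noise
before any fine-tuning.

## Training recipe

Defaults follow the reference recipe: batch size 32, Adam with learning rate
0.001, two-class cross-entropy on the softmax logits (the reference reports
per-class softmax confidences without naming a loss; cross-entropy is the
standard choice), early stopping when validation loss has not improved for 10
epochs, and a cap of 100 epochs — raised to 200 when training from scratch,
which needs longer to converge. Splits are by subject (80/20
train/validation), stratified within capture-experiment groups, so no
subject's videos ever appear on both sides; the split is asserted disjoint on
every call. A group-stratified k-fold driver (`kFoldSubjects()`) is provided
for designs that rotate groups out.

Augmentation draws one random resized crop (80–100% of area, aspect ratio
3:4–4:3), one brightness/contrast/saturation jitter triple (±20%/±10%/±10%)
and one horizontal-flip decision (probability 0.5) *per window*, applied
identically to every channel. Per-frame independent augmentation would
destroy the temporal alignment that pooling relies on. Saturation jitter is
drawn for parity with the usual colour-jitter pipeline but is a no-op on
single-intensity channels. The returned weights are those of the
best-validation-loss epoch; when training is warm-started from an inflated
model, the initialization itself competes as "epoch 0", so fine-tuning on
label-noisy windows is only kept if it actually improves validation loss.

Two initialization modes exist because the reference describes both:
single-frame models trained from scratch with Kaiming initialization (after
pretrained ImageNet weights proved unhelpful there), while frame-pooled
training reused pre-trained weights through the patched first layer. The
packaged experiment follows that split: the single-frame baseline trains from
scratch; the pooled model fine-tunes from the baseline's inflated weights.

## The synthetic sweep generator

No public data exist for this task (the source data sit behind a CRADA), so
the generator produces labeled sweeps with the study's capture geometry:
`fps * durationS` frames (30 s × 30 FPS by default) of a bright,
depth-attenuated tissue field containing a dark elliptical organ whose center
drifts sinusoidally by `organDriftAmplitude` pixels (probe motion), all
multiplied by per-pixel Rayleigh speckle and quantized to 8 bits. Rayleigh
multiplicative speckle is the standard first-order model of fully developed
B-mode texture; its scale defaults to $\sqrt{2/\pi}$ so the multiplier has
unit mean, and its point SNR (≈1.91) is fixed by the distribution's shape.

For positive videos an anechoic crescent is rendered lateral to the organ in
exactly `round(fluidVisibilityFraction * T)` frames, chosen as one contiguous
block — the cue enters and leaves the imaging plane during a sweep rather
than flickering frame to frame. Each positive video also draws a severity
multiplier (`severityRange`, default 0.5–1.5× the nominal `fluidContrast`),
emulating the clinical spread from slight small pockets to obvious
accumulations that the source data's curation explicitly recorded. The
generator emits a ground-truth side channel (which frames render the cue, and
the nominal cue region) used only by oracle tests; the classifier path never
reads it.

Difficulty calibration was done once, with the generator's own region-mean
oracle rather than any trained model: the crescent (an elliptical shell
1.10–1.30× the organ radii, restricted to the lateral sector; ~99 pixels at
64×64) and the nominal contrast 0.25 put single-frame detection in the noisy
regime while a 15-frame average detects reliably — the regime the method is
designed for. What the generator does *not* emulate: anatomically realistic
organ shapes, acoustic physics (attenuation, shadowing, time-gain
compensation), inter-subject anatomical variability, or operator-dependent
probe handling. Passing the packaged experiment therefore demonstrates that
the pipeline recovers an intermittently visible low-contrast cue from pooled
frames under speckle — not clinical performance.

## The packaged pooling-benefit experiment

`poolingBenefitConfig()` fixes the desk-scale study conditions: 8 subjects ×
4 videos of 64×64, 3-s sweeps at 30 FPS (90 frames), even class balance,
cue visible in 20% of positive-video frames. Three subjects are held out for
evaluation; the remaining five are split 80/20 by subject. The single-frame
baseline (n = 1, stride 3) trains from scratch for up to 50 epochs; the
pooled model (n = 15, stride 3) fine-tunes from the baseline's inflated
weights for up to 12 epochs. Both models score the held-out videos with
overlapping windows at the training stride — with an intermittent cue, the
single 30-s-stride window of the real-time recipe could miss the cue block
entirely at this short video length — and each model's operating threshold is
identified by an F1 sweep over its evaluation scores, mirroring the
reference's threshold optimization on the real-time test set. Accuracy, the
ROC/AUC, and the exact McNemar comparison are computed on the same videos.

Problem sizes here (90-frame videos, 32×32 inputs, hundreds of windows) were
chosen so a full replicate runs in about a minute on one CPU core; the
acceptance suite repeats the experiment over five seeds and expects the
pooled model to beat the single-frame baseline in at least four.

## Numerical and design choices

* **Tie at the threshold** — a video score exactly at $\tau$ is called
  positive, consistent with reading any suspicion of injury as positive.
* **Padded windows** contribute to the video average with equal weight; the
  reference is silent, and down-weighting would complicate the permutation
  invariance of the aggregation.
* **Undefined ratios** (empty denominators in precision/sensitivity/F1, an
  absent class row in a normalized confusion matrix) surface as `NaN` plus an
  explicit flag, never as a silent 0.
* **Exact McNemar** by direct binomial tail
  ($p = \min(1,\, 2\,P[X \le \min(b,c)]$, $X \sim \mathrm{Bin}(b+c, 1/2)$)
  because the video counts involved are small; the continuity-corrected
  chi-square variant is available for cross-checking. No discordant pairs
  gives $p = 1$ with a degeneracy flag.
* **Threshold sweep grid** defaults to the achievable operating points (the
  sorted unique scores plus 0/1), since averaged softmax scores can occupy a
  narrow band that a fixed coarse grid cannot resolve; ties select the lower
  threshold.
* **ROC** uses "positive iff score ≥ t" over the unique scores plus
  sentinels; the trapezoidal area then equals the Mann–Whitney probability
  with half-credit for ties, which the tests verify pairwise.
* **Determinism** — every stochastic step (simulation, splits,
  initialization, shuffling, augmentation) derives its seed from the
  experiment seed; reruns of `runExperiment()` with one configuration are
  byte-identical, and all CSV/JSON artifacts embed the configuration hash.
* **Convolution engine** — forward and backward passes are im2col gathers
  followed by BLAS matrix products; the backward-data pass of a stride-1
  convolution is a convolution with spatially rotated, channel-transposed
  kernels, so one primitive serves both directions. Gradients are verified
  against numerical differentiation in the test suite.

## Known limitations

The EfficientNet backbones of the reference are out of scope here — there is
no deep-learning framework among this package's dependencies, and no
pretrained weights to inflate — so `tiny_cnn` is the supported backbone and
the inflation rule is exercised against seeded synthetic source networks.
Real variable-length clips (the reference's RUQ videos are not uniformly 900
frames) are supported by the windowing (`n > T` pads; any `T` works), but the
generator emits fixed-length videos only. With 12 held-out videos per
replicate, per-seed accuracy estimates are coarse (granularity 1/12) and the
McNemar test is underpowered — the acceptance property therefore aggregates
over replicate seeds rather than reading any single p-value.
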