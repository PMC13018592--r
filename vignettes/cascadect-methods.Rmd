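---
title: "CascadeCT: model, calibration, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CascadeCT: model, calibration, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

CascadeCT classifies 2-D grayscale CT slices (values in [0, 1]) as ischemic
stroke or normal, and wraps the classifier in a cascaded decision pipeline
that quantifies uncertainty and audits its own attention before committing
to a label. This vignette records the model, the calibrated quantities, and
the design decisions that were genuinely open, in the package's own words.

## The classifier

The network is a stack of residual blocks. Each block applies a 3×3
convolution (stride 1, size-preserving padding), batch normalization, and a
ReLU; the result is added to the block input (through a 1×1 projection
convolution only when the channel counts differ, identity otherwise). No
second nonlinearity follows the addition. Dropout is applied after the
residual addition — this placement is what later makes Monte-Carlo
inference perturb whole block outputs — followed by 2×2 max pooling. After
the last block, adaptive average pooling to a 2×2 grid makes the head
independent of input resolution, a linear layer maps to a 128-dimensional
latent vector (no activation, so the latent space stays linearly readable),
and a 2-class softmax head produces probabilities. Logits are retained
internally for temperature scaling.

The pinned configuration — five blocks of 128 channels, projection at block
1 only (1 → 128), kernel 3, adaptive pool 2×2, latent 128 — has exactly
659,074 trainable parameters (1,792 + 4×147,840 + 65,664 + 258), i.e. 0.66 M
to two decimals. Batch-norm running statistics are buffers and are never
counted. All channel widths, kernel size, block count, pool size and head
widths are configurable, so ablation variants (e.g. 64/128/256 channels)
are a configuration change, not a code change.

The engine itself — im2col convolution as one BLAS product per layer,
batch-norm forward/backward, max and adaptive pooling, softmax
cross-entropy, Adam — is written in base R. The backward pass is verified
against central finite differences in the development process, and the
parameter count against an independent shape-arithmetic oracle in the test
suite. Training minimizes cross-entropy with Adam, keeps the
best-validation-loss weights, and is bit-reproducible given the seed: all
stochasticity (shuffling, dropout masks, initialization) flows from R's RNG.

Package defaults follow common practice (Adam, learning rate 1e-3, batch
32, patience 10). At the reduced problem sizes used in the tests (below),
convergence is more reliable with a learning rate of 3e-3 and batches of
4–8 — small batches give more optimizer steps per epoch on small datasets —
so the test fixtures set those explicitly.

## Monte-Carlo-dropout uncertainty

At inference, dropout is re-enabled at a rate p and the image is passed N
times; the per-pass softmax vectors are averaged into the predictive
distribution, and uncertainty is the normalized entropy

H = −Σ_c p_c log p_c / log C ∈ [0, 1],

with 0·log 0 := 0. The division by log C is deliberate: plain Shannon
entropy of a two-class distribution tops out at log 2, and the stated
[0, 1] interpretation (0 = certain, 1 = maximally uncertain) only holds
after normalization. N = 20 is the default; an accuracy-versus-N sweep
(`sweepForwardPasses`) uses nested pass streams (pass n depends only on the
seed and n), so the first 10 passes of an N = 20 run *are* the N = 10 run
and saturation can be read off one set of simulations.

The inference rate p\* is selected from the grid
{0.01, 0.05, 0.1, 0.2, 0.3, 0.5} by scoring, at each rate, the separation
between the entropy distributions of correctly and incorrectly classified
validation images. Separation is quantified as the probability that a
random misclassified image has higher entropy than a random correct one
(ties half-weighted) — the area under the ROC curve of H as an error
detector — because a boxplot comparison needs a number to be automated.
Correctness here is judged against the MC mean prediction, not the
deterministic one, since the rate being tuned is the one used at MC
inference. Ties select the smaller rate; if no validation image is ever
misclassified the smallest rate is selected with a recorded warning.

The rejection threshold α is the mean normalized entropy of the validation
set at p\*. Predictions with H ≤ α are reliable (inclusive, so α = 1
retains everything); H > α is flagged for expert review and excluded from
automated output. Computing α on validation rather than on the incoming
test batch avoids test-time leakage and keeps the threshold frozen between
runs.

## Quantitative saliency

Grad-CAM explains a class score c at the last residual block's ReLU feature
maps: channel weights are the spatial means of ∂score_c/∂A_k, the map is
ReLU(Σ_k w_k A_k), bilinearly upsampled to the image and min–max normalized
to [0, 1]. A constant raw map normalizes to all-zeros rather than dividing
by zero. Grad-CAM++ uses the per-pixel higher-order weighting built from
elementwise powers of the gradient; Score-CAM weighs each channel by the
class-score increase of the input masked by that channel's normalized
activation (weights are computed with deterministic forward passes in both
modes; stochasticity enters Score-CAM through the activations). The
explained class defaults to the model's prediction, which is the class the
correction rule reasons about. The target layer is the last block's
convolutional features, the standard choice for class-discriminative maps.

The Mean Saliency Intensity of a normalized map, MSI = (1/UV) Σ C_ij, is
low for focal attention and high for diffuse, indiscriminate attention.
The decision threshold is D = min(max MSI over validation true positives,
max MSI over validation true negatives): a retained prediction whose MSI
exceeds the largest MSI seen among *correct* validation cases of either
kind is attending too diffusely to be trusted, and its binary label is
flipped. Equality keeps the prediction — the conservative reading that
minimizes interventions. The MSI that feeds the rule is computed from the
MCD-mode map (per-pass maps normalized, averaged, renormalized; with p = 0
this equals the deterministic map bit-for-bit) at p\*; the deterministic
MSI is also recorded for comparison. D is fitted on validation, where
outcomes are known, and applied to every retained test prediction —
restricting the flip to known misclassifications would be circular at
inference time.

Pearson correlation between deterministic and MCD maps is available as a
consistency check (`saliencyPCC`), reported as missing for constant maps.

## The cascade

`fitCascade` calibrates sequentially on the validation split: p\* (entropy
separation) → α (mean entropy at p\*) → D (MSI of validation TP/TN at p\*).
`runCascade` then processes each image: MC prediction at (N, p\*) →
if H > α, flag for review and stop (the saliency stage never sees flagged
cases) → otherwise compute the MCD Grad-CAM MSI → flip if MSI > D, accept
otherwise. Every image ends in exactly one of accepted / flipped /
flagged_for_review; flagged cases are reported, never dropped, and the
evaluation utilities offer both retained-only and abstention-counting
views. Setting α = 1 and D = 1 provably reduces the cascade to plain MC
classification, which the tests assert exactly.

## Evaluation

Classification metrics use stroke as the positive class; each proportion
carries a 95% Wilson score interval (exact normal quantile 1.959964…),
which is well behaved at 0/n and n/n — the lower bound at 100/100 is
96.30%, at 93/93 it is 96.03%. Metrics with zero denominators are reported
as undefined, never as 0. F1 is the harmonic mean of precision and
sensitivity and equals 2tp/(2tp+fp+fn) exactly.

MoRF (most-relevant-first) curves remove the top-f fraction of pixels in
saliency order (ties broken row-major), replace them with the dataset mean
intensity (a zero replacement is available by flag), and track the
deterministic confidence of the originally predicted class over
f ∈ {0, 0.05, …, 1}. The area under the mean curve (AUPC, trapezoidal on
the unit square, hence in [0, 1]) ranks attribution methods; lower is more
faithful, ties prefer Grad-CAM. A plain sum of mean confidences over the
grid is also reported (`aupcStepSum`) since some reports quote that scale
(tens rather than unit fractions); both orderings coincide.

Calibration: ECE with 10 equal-width confidence bins (empty bins skipped),
MCE as the worst bin gap, Brier as the squared error of the positive-class
probability (the binary convention). Temperature scaling minimizes
validation NLL of softmax(logits/T) over T ∈ [0.05, 20] to 1e-4; being a
monotone transform it never changes argmax decisions, which is asserted.
Risk–coverage sweeps the entropy threshold over all observed values plus
{0, 1}; coverage is the retained fraction, risk is 1 − accuracy among
retained, undefined at zero coverage.

## Synthetic phantoms

The generator emulates a normalized axial CT slice: dark background, a
bright skull annulus (0.95 before noise), parenchyma at 0.5 textured by a
Gaussian-smoothed random field (amplitude 0.035, smoothing length
`textureScale` pixels), and — for the stroke class — one connected
hypodense blob with a cosine-tapered edge, placed uniformly inside the
brain so that blob plus taper stay within the parenchyma. Inside the binary
ground-truth mask the decrement equals `lesionContrast` exactly (the taper
lies outside the mask), so a matched normal phantom with the same seed
differs only by the lesion — that is what makes contrast assertions and
lesion-overlap tests exact. Additive Gaussian noise and clipping to [0, 1]
come last. Same parameters + same seed ⇒ bit-identical phantoms.

The default difficulty mix is 60% easy cases (contrast drawn uniformly in
0.15–0.25) and 40% hard (0.03–0.08): easy cases give the classifier
confident detections, hard cases produce genuine errors and high-entropy
predictions, so the rejection and flip stages have real work. Datasets are
persisted as lossless 8-bit PNGs (pixel = round(value·255)) with the split
manifest as CSV, a JSON parameter sidecar, and an exact double-precision
array bundle for bit-exact round trips.

What the phantoms do *not* model: 3-D structure, anatomy (ventricles,
sulci), beam-hardening or motion artefacts, and the label noise of real
annotations. Passing tests on phantoms therefore demonstrates that the
pipeline's statistical machinery behaves as specified — not that any
particular accuracy transfers to clinical CT.

## Problem sizes used by the tests

The test suite and acceptance checks run at reduced, fixed conditions
chosen once: 32×32 phantoms (the architecture is resolution-agnostic via
adaptive pooling; 224 is the deployment default, 96 a fast compromise),
networks of 2–3 blocks at 6–32 channels for trained fixtures, N = 20
MC passes with the full dropout grid for calibration, 200-image training
sets, and a 400-image mixed-difficulty test set repeated over 5 seeds for
the rejection-safety property. The pinned 5×128 architecture is always
used for parameter-count checks; it is simply not trained in the tests.

## Known limitations

* Binary decisions only; the flip rule is meaningful only with two classes.
* The R engine favours clarity and reproducibility over throughput; it is
  adequate for phantom-scale studies, not for training at 224×224 on large
  archives.
* Score-CAM costs one forward pass per channel and is intended as a
  comparator at small widths.
* MC-dropout captures epistemic uncertainty only; aleatoric noise
  modelling and deep ensembles are out of scope.
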