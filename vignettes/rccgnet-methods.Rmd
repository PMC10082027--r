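---
title: "RCCGNet: model, training protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RCCGNet: model, training protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rccgnet)
```

## The problem

Renal cell carcinoma (RCC) is graded from nuclear morphology: normal
tissue (grade 0) has small, uniform, round nuclei; with increasing grade
the nuclei become larger, more numerous, more pleomorphic (variable in
size), their contours more irregular, and their nucleoli more prominent.
`rccgnet` implements a compact convolutional network that classifies
224×224 H&E-stained histopathology patches into the five grades, together
with the full training, evaluation and visualization protocol around it,
and a synthetic data generator so that the entire pipeline is exercisable
without clinical material.

## The shared-channel residual (SCR) block

The block operates on a feature map $X \in \mathbb{R}^{H\times W\times C}$
with an even channel count:

1. **Convolution.** $Y = \mathrm{ReLU}(\mathrm{BN}(F_{3\times3}(X)))$,
   a same-padded 3×3 convolution at constant width $C$.
2. **Channel split.** $X$ and $Y$ are each split into channel halves
   $[X_1, X_2]$ and $[Y_1, Y_2]$ (channels $1..C/2$ and $C/2+1..C$).
3. **Sharing.** The halves are exchanged *across layers*:
   $X_{cat} = [X_1, Y_2]$ and $Y_{cat} = [Y_1, X_2]$. The operation is
   parameter-free, conserves the channel multiset, and is an involution.
4. **Two paths.** Each concatenation passes through its own
   conv–BN–ReLU: $X_{SC}$, $Y_{SC}$.
5. **Gating.** Each path is rescaled per channel by
   $\sigma(W\,\mathrm{gap}(\mathrm{BN}_g(\cdot)) + b)$, where
   $\mathrm{gap}$ is global average pooling and $W$ a 1×1 convolution
   ($C\times C$) with bias. Since $\sigma \in (0,1)$ the gate never
   amplifies an activation.
6. **Residual.** $\mathrm{Out} = X_{out} + Y_{out} + X$.

With every convolution weight at zero and batch norm at its identity
initialization the block is exactly the identity map — the residual path
guarantees gradient flow at depth.

Two presentation ambiguities in the block's published equations were
resolved as follows (both switchable):

* The second concatenation is implemented from its printed *element
  listing* $[y^1..y^{C/2}, x^{C/2+1}..x^C]$, which matches the prose,
  rather than its (inconsistent) label.
* Each path is gated by *its own* pooled statistics. The literal
  equation form, in which the X-path gate also scales the Y path (and
  the Y gate is dead code), is available via
  `network_config(strict_gate = TRUE)` for reproduction studies.

## Macro-architecture

The published architecture figure is schematic, so the layer order and
repeats were fixed against the model's published complexity budget
(0.3651 M parameters, 4.48 G FLOPs at 224×224×3 with 2 FLOPs per
multiply–accumulate), which the package treats as the authoritative
specification:

```
stem    3×3 conv 3→16, BN, ReLU                       @224
stage 1 SCR(16) × 2                                    @224
        2×2 max-pool; 3×3 conv 16→32, BN, ReLU         @112
stage 2 SCR(32) × 2                                    @112
        2×2 max-pool; 3×3 conv 32→64, BN, ReLU         @56
stage 3 SCR(64) × 2                                    @56
head    global average pool → dense 384 (ReLU) → dense 5 → softmax
```

All spatial convolutions are bias-free (they are followed by batch
norm); the gate's 1×1 convolution keeps its bias. This assembly has
exactly 365,077 trainable parameters (0.3651 M) and 4.495×10⁹ FLOPs
(within 0.4 % of the published 4.48 G):

```{r}
m <- build_rccgnet(network_config(), seed = 1)
count_parameters(m)        # 365077
count_flops(m, 224) / 1e9  # 4.4946
model_summary(m)
```

FLOP conventions: convolutions contribute
$2\,H_{out}W_{out}C_{out}C_{in}k^2$, dense layers $2\,n_{in}n_{out}$
(+bias), batch norm 2 per element, activations and pooling 1 per
element; totals are reported to 3 significant digits.

### Ablation variants

* `cnn1_no_sharing`: the two paths process $X$ and $Y$ directly
  (sharing is a rearrangement, so the parameter count is unchanged).
* `cnn2_no_gating`: the gates are removed (strictly fewer parameters).
* `cnn3_no_scr`: each SCR block is replaced by two plain conv–BN–ReLU
  layers of matched width.

### A note on the gate's normalization

The channel gate carries a batch-norm stage (this is part of the
parameter budget above). It is placed on the gating branch's *spatial
input*, before pooling, where batch statistics are estimated from
$H\cdot W\cdot N$ values per channel. Normalizing *after* pooling would
standardize per-sample summary statistics across a batch of four — the
gate then learns batch-relative context that does not exist at
inference, which measurably destroys test-time accuracy while leaving
training accuracy intact. This placement was selected on that
train/inference-consistency argument.

## Training protocol

`train_config()` defaults encode the published protocol: Adam
(learning rate 0.001, $\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\epsilon = 10^{-7}$), batch size 4, at most 65 epochs, softmax
cross-entropy. Two callbacks monitor validation accuracy with
min-delta $10^{-4}$ (an improvement must be *strictly* larger):

* **Reduce-LR-on-plateau**: after 5 consecutive non-improving epochs
  the learning rate is halved (factor 0.5, no lower floor); the
  counter then resets. Every change is exactly a halving, so the
  learning-rate sequence is non-increasing.
* **Early stopping / checkpoint**: the best weights are snapshotted on
  every improvement (and persisted when a checkpoint path is set);
  after 30 non-improving epochs training stops and the snapshot is
  restored bitwise. The two callbacks keep independent counters.

Batch-norm running statistics use momentum 0.9. The commonly used 0.99
converges those statistics over thousands of optimizer steps; the
desk-scale runs in this package take a few hundred, where 0.99 leaves
inference-mode normalization badly stale. The choice affects no
complexity figure.

The engine runs its convolution GEMMs in single precision by default
(`precision = "single"`); `precision = "double"` exists for numerical
work such as finite-difference gradient verification.

## Data pipeline

Images are ingested from one-folder-per-class trees (PNG natively;
JPEG/TIFF via EBImage). Processing follows the study's protocol:
non-overlapping square tiles (partial edge tiles dropped; an image
smaller than one tile is resized whole), per-patch normalization to
zero mean and unit variance (a dataset-level alternative is not
provided because the study normalizes patches), stratified 80/20
train/test split, and a validation set built by cropping a fixed
corner region of each training patch that is pixel-disjoint from the
designated training region, resized back to full size. Training-set
augmentation emits the original, horizontal and vertical flip of every
patch (exactly 3×; optional seeded random crops give 5×); validation
and test data are never augmented. Stratified k-fold splitting (k = 3
in the study) trains on k−1 folds and tests on the held-out fold.

## Synthetic data

The generator emulates the *morphology gradient* that drives grading,
with per-grade parameters fixed at construction
(see `grade_morphology()`):

| grade | nuclei | mean radius (px @224) | radius CV | contour irregularity | nucleolus prob. |
|------:|-------:|----------------------:|----------:|---------------------:|----------------:|
| 0 | 8–12 | 6 | 0.05 | 0.04 | 0.00 |
| 1 | 10–14 | 7 | 0.10 | 0.10 | 0.05 |
| 2 | 12–16 | 8.5 | 0.16 | 0.18 | 0.30 |
| 3 | 14–18 | 10 | 0.24 | 0.30 | 0.60 |
| 4 | 16–22 | 12 | 0.35 | 0.45 | 0.90 |

Nuclei are drawn as radial Fourier perturbations of circles (the
irregularity parameter scales the boundary perturbation amplitude;
radii are log-normal with the stated CV), over a textured eosin-pink
background, with darker nucleolar spots at grade-scaled probability.
The grade signal is *geometric* — count, size, size variability,
contour irregularity, nucleolar spots — rather than colorimetric, so a
classifier must learn morphology. Each patch records its per-nucleus
boundary statistics, and the measured isoperimetric irregularity
$P^2 / 4\pi A$ rises strictly with grade.

What the generator does **not** emulate: staining variability and
batch effects, tissue architecture (tubules, vessels, stroma),
overlapping nuclei, focus/compression artifacts, scanner noise.
Passing the end-to-end tests therefore demonstrates that the
implementation — network, optimizer, callbacks, metrics — functions
correctly as a learning system, not that it would reach any particular
accuracy on clinical slides.

Default per-class counts (203/135/124/120/140, 722 patches) follow the
grade distribution of the kidney study the package models; a fixed
master seed fans out per-patch sub-seeds, making a dataset
byte-identical across runs.

## Desk-scale problem sizes

The test suite exercises the full protocol at reduced size, chosen
once as the smallest scale at which every contract is still
informative: the end-to-end check trains a 64×64-input network (the
architecture is size-agnostic down to the 4-fold pooling) on the
default 722-patch synthetic dataset for up to 6 epochs without flip
augmentation, and verifies ≥80 % held-out accuracy; because the crop
augmentation that makes zoom-derived validation crops representative is
also dropped at this scale, the callbacks monitor a stratified fifth of
the training patches instead. An overfit sanity check drives a 50-patch
subset to 100 % training accuracy with the standard callbacks
monitoring that subset itself. Unit tests use
8–32 px inputs and single-stage variants. The published complexity
figures are always computed at the full 224 px input — they are
analytic and cost nothing.

## Numerical choices and degenerate inputs

* Batch-norm $\epsilon = 10^{-3}$; normalization-guard
  $\epsilon = 10^{-7}$ for patch standardization; cross-entropy clips
  probabilities at $10^{-12}$; softmax subtracts the maximum logit.
* Odd channel counts are rejected (the split requires evenness), as
  are class counts below 2 and empty training splits.
* Zero-denominator metrics (empty class, empty prediction column)
  report 0 with a `degenerate` flag rather than NaN, keeping reports
  stable on tiny runs; AUC for a class absent from the truth is `NA`
  and excluded from the mean with a warning.
* Quartiles use linear interpolation (R type 7). Bilinear resampling
  uses pixel-center alignment.
* Grad-CAM normalizes each map to [0, 1] unless it is identically
  zero, which is preserved as all-zero.

## Known limitations

* Inference and training run on CPU; wall-clock cost is dominated by
  stage-1 convolutions at full resolution. Throughput is adequate for
  desk-scale experiments, not for slide-scale screening.
* The macro-architecture is a reconstruction constrained by the
  published budget; within that budget the hidden dense width (384)
  and the gate-normalization placement are package choices.
* Patch-level (not patient-level) splitting, matching the study
  protocol; on clinical data patient-level leakage control would be
  required.
* JPEG ingestion requires EBImage.
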