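---
title: "ESTAN: model, evaluation protocol and synthetic phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ESTAN: model, evaluation protocol and synthetic phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estan)
```

## The problem

Breast ultrasound (BUS) tumor segmentation is hard exactly where it
matters most clinically: small tumors. Early-stage tumors occupy a small
fraction of the image, resemble normal hypoechoic tissue, and sit inside
a strongly anisotropic scene — BUS images are a vertical stack of tissue
layers (skin, premammary/subcutaneous fat, mammary, retromammary) whose
echo texture propagates horizontally. Generic encoder-decoder networks
built from square kernels aggregate context across several anatomical
layers at once, which both dilutes small-tumor evidence and invites
false positives from tumor-like regions in other layers.

The Enhanced Small Tumor-Aware Network (ESTAN) addresses this with two
parallel encoders whose features are fused in a shared decoder:

* the **basic encoder** is a conventional contracting path — per block,
  two 3×3 ReLU convolutions and a 2×2 max pooling, with 32, 64, 128,
  256 and 512 kernels in blocks 1–5 and no pooling in block 5;
* the **ESTAN encoder** replaces each block by two parallel branches:
  a small-square-kernel branch (two stacked ReLU convolutions, sizes
  A1 and A2) and a **row-column-wise** branch (an A3×1 vertical
  convolution followed by a 1×A3 horizontal one, then an A4 square
  convolution). The branches are summed element-wise and fused by a
  final convolution of size A5, adding a third nonlinearity to the
  block's main path. The 1-D kernel length A3 shrinks with depth —
  15, 13, 11, 9, 7 — as the feature maps shrink; A5 is 5 in blocks 2
  and 5 and 1 elsewhere.

The row-column-wise pair is the anatomy prior: a long vertical kernel
spans layer boundaries while a long horizontal kernel follows the
within-layer texture, so features need not be computed over large
square neighbourhoods that straddle several tissue layers.

The decoder has four up blocks with 256, 128, 64 and 32 kernels. Each
up block upsamples 2×, concatenates the upsampled features with the
*first* convolution output of the matching basic block and the fused
output of the matching ESTAN block (the first skip connection), applies
a 3×3 convolution, an M2×M2 convolution (M2 = 1, 1, 1, 5 per block;
the channel-controlling layer after the big concatenation), then
concatenates the *second* convolution output of the basic block (the
second skip connection) before a final 3×3 convolution. A 1×1
convolution plus sigmoid produces the per-pixel tumor probability. All
convolutions are zero-padded "same", so a 256×256 input yields a
256×256 probability map, with a 16×16×(2·512) bottleneck after four
pooling stages.

## Design choices the schedules leave open

The published schedules pin down most, but not all, of the
architecture. Where they are silent this package made one choice,
exposed it in `net_config()`, and kept it fixed:

* **A1, A2, A4** (the "four square kernels" of an ESTAN block) are not
  printed; we use 3, 3, 3 — small squares, consistent with the design
  goal of avoiding large square receptive fields.
* **Branch merge** is the element-wise sum written in the block
  equation, not a concatenation; both branches therefore emit the
  block's full channel count.
* **Bottleneck fusion**: how the two block-5 outputs jointly enter the
  first up block is unstated; we concatenate them (1024 channels at
  16×16 for the default width), letting the decoder's
  channel-controlling convolutions do the mixing.
* **Upsampling** is a 2×2 stride-2 transposed convolution by default;
  a parameter-free nearest-neighbour variant is available
  (`upsample = "nearest"`).
* **Padding** is zero "same" everywhere — required for the printed
  shape bookkeeping to work out; **pooling** in the ESTAN encoder is
  max pooling, mirroring the basic encoder; **no batch normalization**
  (none is described); **He-uniform** initialization with a seed.
* The row-column branch's receptive field: because the two 1-D
  convolutions are composed, the branch's footprint is the full
  A3×A3 window (the composition of a vertical and a horizontal kernel
  is separable), and that is the property the tests verify by
  perturbation in the linear regime.

The network core (convolution forward/backward as shifted GEMMs,
pooling, transposed convolution, Adam) is implemented in C++ with
RcppArmadillo inside the package; the fixed topology lets the backward
pass be written explicitly rather than through a general autograd
graph, and a finite-difference test pins its correctness.

## Training

Training minimizes the soft Dice loss
`1 - (2·Σ p·t + ε) / (Σ p + Σ t + ε)` with ε = 1 by default, by
mini-batch Adam. The published protocol states the loss, the 256×256
input size and five-fold cross-validation, but no optimizer,
learning-rate, batch-size or epoch settings; the package defaults to
Adam with learning rate 1e-4, batch 8, 100 epochs, no augmentation,
all exposed in `train_config()` and all funnelled through explicit
seeds (fold split, per-fold initialization, shuffling, phantoms), so a
single-threaded run is byte-reproducible. Per fold, the model is
reinitialized from a fold-specific seed; no weights are shared across
folds. For the capacity and smoke tests we use a learning rate of
1e-3 with batch 4, which overfits eight 64×64 phantoms within a few
dozen epochs.

## Evaluation protocol

Seven metrics per image, computed at the working resolution (256×256
by default; configurable) against a nonempty ground-truth mask:

* **TPR** = TP/|GT|, **JI** = TP/(TP+FP+FN), **DSC** = 2TP/(2TP+FP+FN);
* **FPR** = FP/|GT| — the BUS convention divides by the *actual
  positives*, not the negatives, so FPR exceeds 1 whenever the spurious
  region outgrows the tumor;
* **AER** = (FP+FN)/|GT| = FPR + (1 − TPR);
* **HD**, the exact (max–min) symmetric Hausdorff distance between the
  4-neighbour boundary pixel sets, and **MAE**, the average symmetric
  boundary distance. "Hausdorff" is sometimes reported as an averaged
  variant elsewhere; we use the exact maximum and report the mean
  separately as MAE.

Empty *predictions* get their natural area metrics (TPR = FPR = 0,
AER = 1) but undefined boundary distances; those are flagged, excluded
from HD/MAE averages, and the exclusion count is reported. Samples with
empty *ground truth* (e.g. tumor-free images) are skipped with a logged
reason — the FPR convention presumes a tumor is present.

Tumor size is the **longest axis**: the Feret diameter (maximum
pairwise distance between foreground pixel centers) of the mask at the
*original* resolution, measured per connected component with the
maximum reported. A fitted-ellipse major axis is the obvious
alternative reading of "longest axis"; the Feret diameter is chosen
because it is parameter-free and equals the brute-force all-pairs
maximum, which the tests exploit. Size groups tile the positive axis
with half-open-above intervals (0,100], (100,120], (120,160],
(160,∞), and *small* means ≤ 120 px. Inclusivity at the boundary is
chosen so the two small groups' benchmark counts (19 + 30) add up to
the published small-tumor count (49), which only happens when 120 px is
itself small.

Method comparison uses the two-sided Wilcoxon signed-rank test on
paired per-image metric values (per-image, rather than per-fold means,
which the protocol leaves unstated), with zero differences discarded
and midranks for ties. For up to 12 remaining pairs the null is
enumerated over all 2^n sign assignments — exact even under ties; above
that, the normal approximation with tie and continuity corrections.
P-values are Holm–Bonferroni adjusted across metrics at α = 0.05.

## The synthetic phantom

`generate_phantom()` builds a 500×500 (by default) scene of four
horizontal bands with fractions 0.08/0.18/0.50/0.24 and mean
echogenicities 0.80/0.35/0.55/0.30 (bright thin skin, dark fat,
mid-bright mammary, darker retromammary). The tumor is a hypoechoic
ellipse centered inside the mammary band: its radius is modulated by a
random low-order harmonic series (harmonics 2–5, normalized so the
peak relative perturbation equals `boundary_irregularity`), its outline
is rescaled analytically so the realized Feret diameter matches the
requested `tumor_axis_px` to rasterization error, its intensity is
reduced by `tumor_contrast`, and an optional column-wise exponential
attenuation below the tumor imitates posterior shadowing (off by
default). Speckle is a unit-mean gamma field (shape 4), Gaussian
smoothed (σ = 1.5 px) to give it grain, renormalized to unit mean and
multiplied into the clean template — a standard multiplicative proxy
for ultrasound speckle, chosen because the benchmark datasets are real
images and no noise model is published. With speckle disabled the image
is exactly the clean band-plus-tumor template, which the tests use to
verify the multiplicative structure.

`generate_dataset()` draws axis lengths from a right-skewed log-normal
(meanlog = log 110, sdlog = 0.45, clamped to [40, 0.45·side]) whose
mode sits below 100 px at the 500-px reference resolution — emulating
the positively skewed clinical size distributions in which most tumors
are smaller than 150 px — and randomizes aspect (0.5–0.95), orientation,
irregularity (0.05–0.2) and contrast (0.25–0.5) per sample, with
per-sample seeds derived from one master seed.

What the phantom does **not** emulate: wave physics (refraction,
reverberation, anisotropic point-spread), heterogeneous within-layer
structures (Cooper's ligaments, ducts), calcifications, multiple or
non-elliptical lesion topologies, and the benign/malignant appearance
axis. Passing tests on phantoms therefore demonstrate that the
architecture, losses, metrics and harness are implemented correctly
and that the network can learn layered-scene segmentation — they say
nothing about clinical performance, which requires the real benchmark
datasets and full-scale training.

## Numerical choices and problem sizes

* Binarization threshold 0.5 (configurable); lowering it can only grow
  the predicted region (nestedness is tested).
* Dice ε = 1: loss at a perfect prediction is ε/(2|GT|+ε) > 0 and
  decreases monotonically to 0 as ε → 0 (tested).
* Pooling requires even sides; the input side must be divisible by 16,
  and `resize_for_net()` refuses sides below 16.
* Ties in max pooling resolve to the first maximum in top-left →
  bottom-right order; Holm adjustment resolves p-value ties by the
  cumulative-maximum recursion.
* Exact/approximate Wilcoxon crossover at n = 12 (4096 enumerated
  patterns), a few milliseconds.
* The capacity checks run a width-reduced model (channels ÷ 4:
  8–128, decoder 64–8) at 64×64 on CPU: it overfits 8 phantoms to
  training DSC > 0.9 (early-stopped once DSC ≥ 0.95), and a 20-phantom
  2-fold cross-validation with 30 epochs exercises the whole pipeline;
  the determinism check repeats a 10-phantom, 6-epoch, 2-fold pipeline
  at 32×32 twice and compares CSVs byte-for-byte. These sizes were
  chosen as the smallest at which the capacity and accounting
  properties are clearly expressed.

## Known limitations

* The full-width network (≈ 33.8 M parameters) is buildable and
  runnable (a 256×256 forward pass takes seconds on one CPU), but
  training it to benchmark quality requires GPU-scale compute and the
  real clinical datasets; the package's empirical claims are limited to
  what its tests and acceptance script compute on phantoms.
* The per-image loop keeps activations for the backward pass in
  memory; at 256×256 full width this is fine, but very large images
  would need activation checkpointing, which is not implemented.
* Only single-channel inputs and binary masks are supported; no DICOM
  ingestion, no multi-class segmentation, no other multiple-testing
  corrections than Holm.
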