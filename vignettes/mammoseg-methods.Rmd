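---
title: "Multitask mammographic density estimation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitask mammographic density estimation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammoseg)
```

## The problem

Mammographic percent density (PD) is the fraction of the breast area
occupied by fibroglandular ("dense") tissue. It is both a strong risk
factor for breast cancer and a quantity whose visual assessment is noisy:
two readers often disagree by several percentage points, and category-based
BI-RADS ratings are coarse. An automatic estimator needs two segmentations
of the same mammogram — the breast area (excluding the pectoral muscle,
which in mediolateral-oblique (MLO) views is a bright wedge with intensity
similar to dense tissue) and the dense tissue within it — after which PD is
a pixel-count ratio:

$$\mathrm{PD} = \frac{\sum_j \hat y_d^{(j)}}{\sum_j \hat y_b^{(j)}} \times 100.$$

`mammoseg` treats the two segmentations as one multitask learning problem:
dense-tissue segmentation is the *main* task and breast-area segmentation
the *auxiliary* task, sharing an encoder so that features that delineate
the breast boundary and pectoral edge also inform the dense-tissue head.

## Architecture

`network_config()` describes the network; `build_model()` instantiates it.

* **Encoder** — `depth` stages (default 4; the desk-scale studies in this
  package use 2). Stage $i$ is a *multilevel dilated residual* (MDR)
  block at width `base_width`·2^(i−1) followed by 2×2 max pooling. An MDR
  block runs parallel 3×3 convolutions at the configured dilation rates
  (default 1 and 3), each followed by normalisation and a rectifier,
  concatenates the branches, fuses them with a 1×1 convolution, and adds a
  residual shortcut (identity when channel counts match, 1×1 projection
  otherwise). With all convolution weights zero a block reduces exactly to
  its shortcut — a property the tests assert.
* **Bottleneck** — the same block structure at parallel dilation rates
  1, 3, 5, widening the receptive field at the coarsest resolution.
* **Decoders** — one per task, structurally identical but
  parameter-independent: transpose-convolution (2×2, stride 2) upsampling,
  concatenation of the matching encoder skip features, an MDR block, and a
  final 1×1 convolution with a two-channel softmax (region of interest,
  background). Probability maps are thresholded at 0.5, ties counting as
  foreground, and restored to the original image resolution
  (nearest-neighbour for masks, bilinear for probability maps).

The exact channel widths and internal wiring of the MDR block are design
choices of this package (the parallel-branch + 1×1-fusion + shortcut form
above); parameter counts are therefore a pure function of the
configuration, not of any external reference. The normalisation layer is a
knob (`batch` by default, or `instance`, `group`,
weight-standardised + group) because small-batch training can favour the
alternatives; all variants are covered by finite-difference gradient
checks in the test suite.

## Losses and task weighting

Each task uses the focal Tversky loss over both classes,

$$L = \sum_{c} \bigl(1 - \mathrm{TI}_c\bigr)^{1/\gamma},\qquad
\mathrm{TI} = \frac{TP + \varphi}{TP + \alpha\,FN + \beta\,FP + \varphi},$$

with $\alpha = 0.3$, $\beta = 0.7$ (penalising false positives more,
which favours recall under class imbalance), $\gamma = 1$ and smoothing
$\varphi = 10^{-6}$. With $\alpha = \beta = 0.5$ the index reduces to the
Dice coefficient — an identity the acceptance tests verify against an
independent counting oracle. Soft probabilities are used during training;
hard masks only for evaluation.

Two combination rules are implemented:

* **Naive**: $L = \lambda L_b + (1-\lambda) L_d$, $\lambda \in (0,1)$,
  with `lambda_grid()` to sweep $\lambda$;
* **Weight-adaptive** (default): the homoscedastic-uncertainty objective
  $L = L_b/\sigma_b^2 + \log\sigma_b + L_d/\sigma_d^2 + \log\sigma_d$.

The uncertainties are parameterised as log-variances $s = \log\sigma^2$
so that optimisation is unconstrained and $\sigma^2 = e^s$ stays positive;
the $\log\sigma$ term is implemented as $s/2$, so checkpointed values are
directly interpretable. For a fixed task loss $L$ the objective is convex
in $s$ with stationary point $\sigma^2 = 2L$ — the tests drive a
gradient-descent-on-$s$-only problem to this closed form. The $1/\sigma^2$
scaling is applied to the training objective only; inference uses the
plain softmax head.

## Training

`mtl_segnet()` is the fitting function. Optimisation is Adam at learning
rate $10^{-3}$ (the optimiser and rate are configuration, not constants —
no hyperparameter search is bundled). One master seed derives the
validation split, the weight initialisation and the per-epoch shuffles, so
a fit is bit-reproducible on a fixed numerical backend. No augmentation is
applied. Model selection keeps the epoch with the best validation F-score
on the dense-tissue task (the main task; the breast task in the
`single_breast` ablation). A non-finite loss aborts with the offending
epoch rather than skipping batches silently. Ablations: `single_breast` /
`single_dense` build only the one decoder; `naive` uses the fixed-λ sum.

## The phantom generator

Real mammogram collections with reader annotations cannot be
redistributed, so the package generates *phantoms* with exact ground
truth. A phantom is a half-elliptical "breast" anchored on the chest-wall
edge against a dark background; dense tissue is the top fraction of a
smooth random Gaussian-blob field ranked over breast pixels, which makes
irregular, blob-like regions whose pixel count hits the target PD exactly
(up to one-pixel rounding, always within the ±2-point generation
tolerance); MLO-style phantoms add a bright triangular pectoral wedge in
the top corner that is *excluded* from the breast mask, reproducing the
classic hard case of pectoral delineation; intensities (background 0.03,
fat 0.35, dense 0.75, pectoral 0.85 by default) are lightly blurred and
perturbed with Gaussian noise (SD 0.02), *after* the masks are fixed, so
ground truth stays exact. Default sampling draws the view uniformly
(CC/MLO), the target PD uniformly on [5, 45] (a realistic screening
range), and 4–10 blobs per image.

Phantoms exercise every contract of the pipeline — nesting of masks,
pectoral exclusion, exact PD bookkeeping, view-stratified evaluation — but
they are *not* photorealistic: they lack vendor-specific intensity
profiles, skin lines, vessels, noise correlation and anatomical texture.
Passing the phantom-recovery tests shows the implementation learns and
measures what it claims; it does not certify clinical performance, which
is dataset-dependent.

## Numerical choices and degenerate inputs

* Resizing: bicubic (Keys kernel, $a=-0.5$) for images, nearest-neighbour
  for masks (so masks remain strictly binary), bilinear for probability
  maps; centre-aligned coordinate mapping with border replication.
  Non-square images are stretched anisotropically to the square model
  input — a stated simplification.
* Intensity normalisation is per-image min–max (optionally restricted to a
  region mask, optionally histogram matching to a reference); a constant
  region yields all zeros with a warning.
* `percent_density()` deliberately does not intersect the masks: if a
  prediction places dense pixels outside the breast, it warns and clips PD
  to 100, keeping PD in [0, 100] while staying faithful to the plain
  count ratio.
* The Otsu baseline zeroes the background through the breast mask, blurs
  with a 5×5 Gaussian ($\sigma = 0.3\,((k-1)/2 - 1) + 0.8$), quantises to
  8 bits and computes the histogram over breast-interior pixels only —
  including the zeroed background would corrupt the histogram.
  Degeneracy (a constant breast interior) is judged *before* blurring,
  because edge blur against the zeroed background would fake contrast; the
  degenerate case returns PD 0 with a warning. Ties in the between-class
  variance resolve to the lowest level.
* Bland–Altman uses the sample (n−1) SD; PD log transforms use
  $\log(\mathrm{PD} + 0.01)$ so PD = 0 is admissible (how zeros should be
  handled is otherwise unspecified; the shift is configurable). Limits of
  agreement are computed on the transformed scale while the CDI acceptance
  rate is always counted on raw percentage-point differences — both are
  reported so the two conventions cannot be conflated.
* The Pearson confidence interval uses the Fisher z-transform with
  standard error $1/\sqrt{n-3}$ (via `stats::cor.test`).
* Segmentation metrics: both masks empty counts as perfect agreement (1),
  exactly one empty as 0, and F = 0 when P = R = 0 — avoiding NaNs in
  dataset means. Aggregation is the image-wise (macro) mean ± sample SD,
  per view and tissue plus a pooled CC–MLO row; spreads are over images,
  not over repeated runs.
* BI-RADS categories use inclusive upper bounds (PD = 25 is category 1).
* Reference PD from two readers: pairs within the ±5-point CDI are
  averaged; others are retained but flagged and excluded from the
  reference.

## Problem sizes used in the bundled studies

The package's own studies run at desk scale, chosen so the full pipeline
(including the end-to-end training criterion) completes in minutes on one
CPU core: 64×64 phantoms, encoder depth 2, base width 8 (≈ 52k
parameters), 200 training / 50 held-out phantoms, batch size 8, 12
epochs. At this scale the model reaches held-out F-scores around 0.99
(breast) and 0.95–0.98 (dense) and a log-scale Pearson r above 0.99
between estimated and true PD — the acceptance script recomputes these
from scratch. The architecture scales to the full 256×256 / depth-4 /
base-64 configuration through `network_config()` unchanged; training at
that scale is a matter of compute, not code.

## Known limitations

* The phantom generator's realism gap (above) means reported numbers
  characterise the implementation, not clinical accuracy.
* Double-precision CPU training only; no GPU kernels, no distributed
  training, no pretrained weights.
* DICOM files are not read directly; convert to PNG/TIFF first.
* Bayesian hyperparameter optimisation and the normalisation-layer
  benchmark are out of scope; the knobs exist but defaults are fixed
  choices.
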