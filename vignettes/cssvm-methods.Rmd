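---
title: "Methods: chameleon-swarm-tuned SVM classification of CT lung nodules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chameleon-swarm-tuned SVM classification of CT lung nodules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the pipeline

`cssvm` implements a complete three-class (normal / benign / malignant)
lung-nodule classification pipeline for 8-bit grayscale CT slices:

1. **Contrast enhancement** — contrast limited adaptive histogram
   equalization (CLAHE);
2. **Segmentation** — fuzzy C-means (FCM) clustering of pixel intensities,
   followed by region-of-interest (ROI) extraction;
3. **Texture description** — the 256-bin local binary pattern (LBP)
   histogram;
4. **Classification** — a soft-margin kernel SVM whose penalty `C` and RBF
   width `gamma` are tuned by the chameleon swarm algorithm (CSA) with
   cross-validated accuracy as the search fitness;
5. **Evaluation** — stratified 10-fold cross-validation with per-class
   one-vs-rest FPR, specificity, sensitivity and recognition accuracy, and
   their macro averages.

Because clinical nodule collections cannot be redistributed, the package
ships a deterministic synthetic phantom generator that reproduces the
*structure* of such data — three classes with an imbalanced 416/120/561
ratio (52/15/70 at the default 1/8 desk scale), benign nodules small,
smooth, round and bright, malignant nodules larger, spiculated and
internally heterogeneous, normal slices lesion-free. Every stage of the
pipeline is therefore testable end to end with no download.

## The phantom generator

A phantom is a `128 x 128` image: a body disc at grey level 150 containing
two darker elliptical lung fields (level 60, geometry jittered per sample),
with additive Gaussian noise (`noise_sigma = 4`) and, for nodule classes, a
bright lesion (level 200) placed uniformly inside a lung field with a
margin so the lesion core never leaks into the body. Benign lesions are
hard discs with radius 4–7 px. Malignant lesions have a core radius of
8–14 px, a smooth low-order boundary modulation bounded at ±0.3 ×
`texture_roughness`, `spiculation_count = 6` Gaussian radial spikes of
amplitude half the core radius, and a smooth multiplicative interior
intensity field — giving LBP a class-discriminative texture, and giving the
boundary the irregularity that distinguishes malignant from benign
morphology. The bound of ±0.3 on the boundary modulation guarantees the
malignant lesion area exceeds every benign lesion area for all seeds, since
the malignant minimum radius is not below the benign maximum.

Default choices and why:

* `noise_sigma = 4`: at this noise level the three intensity strata (lung
  ≈ 60, body ≈ 150, nodule ≈ 200) remain separable by intensity-only FCM —
  a centroid reliably dedicates itself to even the smallest benign lesions
  — while the within-class variation keeps the classification task
  non-trivial: the test suite asserts desk-scale cross-validated accuracy
  above 80 % but below 100 %.
* counts `52/15/70`: the clinical imbalance ratio divided by 8, small
  enough for a complete tuning study in minutes on one CPU.
* Per-sample seeds are `seed + hash(class, index)`, so enlarging one
  class's count never changes any other sample.

What the phantoms do **not** emulate: anatomy (vessels, airways, pleural
attachment), scanner physics (beam hardening, reconstruction kernels),
16-bit HU calibration, 3-D context. A passing test suite therefore
demonstrates the pipeline's correctness and the tuning method's benefit
*under controlled conditions*; it is not evidence of clinical performance.

## CLAHE

Each tile's 256-bin histogram is clipped at `clip_limit × tile_pixels /
256`, the excess is redistributed uniformly over all bins (one pass), and
the mapping is the cumulative clipped histogram scaled to `[0, 255]` with
floor rounding. Per-pixel output bilinearly interpolates the mappings of
the four surrounding tile centres; pixels beyond the outermost centres
clamp to the nearest tile. Images not divisible by the tile grid are
reflection-padded on the bottom/right and cropped after mapping, so no
shrunken border tiles exist. Defaults `tile_grid = (8, 8)`,
`clip_limit = 2` are the conventional CLAHE defaults; both are plain
config. With one tile and an unreached clip limit the operation reduces
exactly to global histogram equalization — the package's test oracle.

The fixed floor-rounding convention makes outputs bit-stable across
platforms; idempotence is *not* claimed (re-equalizing an equalized image
changes it), but each pixel's mapping is monotone in intensity.

## Fuzzy C-means segmentation and ROI extraction

FCM on the 1-D intensity sample minimizes
`J_m = Σ_i Σ_k u_ik^m (x_k − v_i)²` with fuzzifier `m = 2`, alternating the
classical membership and centroid updates until the maximum membership
change drops below `1e-4`. `c = 3` clusters by default — the intensity
strata air/lung, body tissue, lesion. Clustering is intensity-only; a
spatial (intensity, x, y) variant is out of scope.

Numerical choices:

* **Initialization** at the `seq(0, 1, length.out = c)` quantiles —
  extremes included — plus a tiny seeded jitter. Including the extremes is
  deliberate: a lesion occupies well under 3 % of the pixels, and
  mass-weighted initializations (e.g. evenly spaced interior quantiles)
  leave the top centroid stuck splitting the body stratum instead of
  dedicating itself to the small bright mode. Duplicated quantiles share
  one jitter draw so exactly degenerate data (two distinct grey levels)
  keep their centroids coincident and the degenerate case stays
  deterministic.
* **Zero distances** give that pixel a crisp membership (lowest centroid
  index on ties); a centroid with zero total weight keeps its position.
* **Canonicalization**: centroids are sorted ascending and memberships
  reordered, so cluster identity is stable under input permutation.
* The per-iteration objective trace is recorded and asserted non-increasing
  in every test run.

ROI extraction hard-assigns pixels to their maximum-membership cluster,
takes the cluster with the highest centroid, and keeps its largest
4-connected component. The ROI is flagged **empty** — the normal-lung
outcome — when that component has fewer than 9 pixels *or* when the top
centroid is not separated from the next one: the gap fraction
`(v_c − v_{c−1}) / (v_c − v_1)` must reach 0.2. The separation guard is
load-bearing. In a lesion-free noisy image the brightest "cluster" is only
the upper half of the body-tissue noise distribution: roughly half the
body pixels, whose random 4-connected speckle components reach hundreds of
pixels and would otherwise masquerade as an ROI. On phantoms the gap
fraction sits well below 0.2 for lesion-free images and well above it when
a lesion mode exists — the regimes the test suite asserts through
empty/non-empty ROI behaviour per class; both thresholds are exposed as
arguments.

Segmentation runs on the **raw** image, not the CLAHE output: adaptive
equalization redistributes grey levels per tile toward a locally uniform
distribution, which erases the global intensity strata FCM depends on —
on enhanced phantoms the top-centroid gap collapses into the lesion-free
regime for every class. Texture features are then read from the
enhanced image inside the ROI box — enhancement is a texture-contrast aid,
segmentation an intensity-calibrated operation.

## LBP features

The descriptor follows the five-step procedure exactly: for every pixel
with a complete 3×3 neighborhood, each of the 8 neighbors contributes bit 1
iff it is *strictly* brighter than the centre (ties are 0); bits are read
clockwise from the top-left with the first neighbor in the most
significant position; the 256-bin histogram of codes, normalized to sum to
1, is the feature vector. Conventions fixed for reproducibility: square
3×3 neighborhood (the simplest of the stated options), borders skipped
rather than padded, single scale. Strict comparison makes codes invariant
under any strictly increasing intensity transform — tested by property.

When segmentation finds an ROI, codes are computed over its bounding box;
when it is empty (normals) or smaller than 3×3, the whole enhanced image
is used, so lesion-free images still yield a descriptor. A config switch
(`features.use_roi = false`) forces whole-image LBP throughout.

## The chameleon swarm optimizer

CSA is a population optimizer over a bounded box with three movement
stages per iteration, and elitist tracking of the global best `G`:

1. **Prey search**: per element, with probability `1 − Pp` (Pp = 0.1) the
   position takes the exploitation step
   `y + p1 (P − G) r2 + p2 (G − y) r1`, with `P` the personal best and
   `p1, p2 ~ 1.75 U(0,1)`; otherwise an exploratory step
   `mu ((u − l) r3 + l) sgn(rand − 0.5)` with
   `mu = 2 exp(−(4 t/T)^3)` decaying over iterations.
2. **Eye rotation**: each position rotates about `G` by a random angle in
   `[−30°, 30°]` within a random coordinate plane — distance to `G` is
   preserved before clamping. In 1-D, rotation degenerates to seeded
   jitter of at most 1 % of the box width.
3. **Hunting (tongue attack)**:
   `v ← ω v + c1 (G − y) r1 + c2 (P − y) r2` with inertia ω decaying
   linearly 0.9 → 0.4 and `c1 = c2 = 1.75`, then
   `y ← y + (v² − v_prev²) / (2a)` element-wise with acceleration constant
   `a = 2590`.

Every constant above is an overridable hyperparameter; boundary handling
is a hard clamp. Minimization is the internal convention — callers
maximizing accuracy pass the negated objective. The per-stage randomness
derives from a counter-indexed seed, so a full run is reproducible even
when the objective itself consumes random numbers. Benchmarks (tested):
median best fitness below `1e-2` on the 2-D sphere with `n = 20, T = 200`;
the 1-D quadratic optimum located within 0.1 in ≥ 9/10 seeds; and the
swarm beats budget-matched uniform random search on the sphere in ≥ 8/10
paired seeds.

## CS-SVM: hyperparameter search and evaluation protocol

The search space is the classical log2 box `log2 C ∈ [−5, 15]`,
`log2 gamma ∈ [−15, 3]`, decoded by `C = 2^p1, gamma = 2^p2`. The RBF
kernel is the default (a linear mode exists for tests). Fitness of a
position is the negative mean 10-fold accuracy of the decoded
configuration; results are cached on the rounded position. Features are
standardized per dimension with training-fold statistics only — stored on
the model and re-applied at prediction — so held-out folds never touch the
trained fold model (asserted by a sentinel-poisoning test). Multiclass is
one-vs-rest over binary soft-margin machines (libsvm backend), predicting
the class with the largest decision value; the decision-value sign is
calibrated from the backend's internal label order.

Protocol choices:

* The **same** 10 folds serve the tuning fitness and the reported scores.
  This mirrors the single-split protocol typical of this application
  area, and makes "tuned vs untuned on identical folds" a fair paired
  comparison; it does, however, risk optimistically biased absolute
  scores. The honest alternative — tune inside each outer fold — is
  available by building separate fold objects for tuning and scoring.
* The **baseline** "plain SVM" is the untuned default configuration
  `C = 1, gamma = 1/256`: the out-of-the-box setting of common SVM
  implementations, since no baseline parameterization is published for
  this comparison. The comparison is thus defined operationally in-repo.
* Fitness is plain mean accuracy (the evaluated quantity), with class
  imbalance handled by stratified folds, not by reweighting.
* Swarm budget `n = 10, T = 15` (160 objective evaluations, each a full
  10-fold CV) keeps a complete desk-scale tuning run under a minute.
* An optional feature-selection mode appends one position dimension per
  histogram bin, thresholded at 0.5 into an inclusion mask. It is off by
  default: with 160 evaluations a 258-dimensional search is a hook, not a
  recommendation.

## Metrics and the combined table

From the pooled out-of-fold predictions, a 3×3 confusion matrix is built
per technique and collapsed one-vs-rest per class: sensitivity
`100·TP/(TP+FN)`, specificity `100·TN/(TN+FP)`, FPR `100·FP/(FP+TN)` (so
FPR + specificity = 100 identically — the invariant every published
per-class row of this method's reference results satisfies), and accuracy
`100·(TP+TN)/total`. Macro averages are unweighted means of the three
per-class values, rounded half-up to two decimals at render time only.
One-vs-rest is the only standard reading consistent with per-class FPR
and specificity columns reported from a three-class system. Recognition
time is logged per full test-set pass but never asserted — it is
hardware-dependent. Two average cells of the published combined reference
table (the baseline's average FPR and the tuned model's average time) are
arithmetically inconsistent with their own per-class inputs; the package
reproduces the consistent cells and leaves the discrepancy documented
rather than matched.

## Problem sizes used by the tests and the acceptance script

Unit tests run on toys (8×8 to 20×20 images, tens of samples). The
evaluation studies use the full default desk-scale dataset (137 phantoms,
128×128), 10-fold stratified CV, and 10 paired seeds for the
tuned-vs-baseline comparison — the package's own choice of a study size
that completes a full paired tuning study in minutes on a single CPU.

## Known limitations

* Phantom realism is deliberately minimal (see above); absolute accuracy
  numbers on phantoms do not transfer to clinical data.
* Intensity-only FCM cannot separate a lesion whose grey level overlaps
  body tissue; the ROI guard then returns empty and features fall back to
  the whole image.
* The shared-folds protocol couples model selection and evaluation;
  absolute CV accuracies should be read accordingly.
* DICOM reading is not implemented; inputs are 8-bit grayscale PNG.
* Single-scale, non-rotation-invariant LBP; GLCM and multi-scale variants
  are out of scope.
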