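---
title: "Methods: cascaded and ensemble-fused CMF segmentation at desk scale"
author: "cmfelseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cascaded and ensemble-fused CMF segmentation at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`cmfelseg` implements a two-stage, ensemble-fused segmentation pipeline for
craniomaxillofacial (CMF) CT volumes:

1. a **coarse stage** segments ten classes — background, facial soft
   tissue, upper skull, mandible, cervical vertebra, hyoid, pharyngeal
   cavity, inferior alveolar nerve, upper teeth, lower teeth;
2. the **dentition ROI** (bounding box of the upper/lower-teeth foreground,
   dilated by a margin) is cropped and resampled;
3. a **fine stage** with two output heads labels the ROI into 33 classes
   (background + 32 FDI teeth) and 5 classes (background + upper-odd,
   upper-even, lower-odd, lower-even), trained with the combined loss
   `L = lambda1 * Ldice(p33, G33) + lambda2 * Ldice(p5, G5)`;
4. a **combination correction** relabels tooth components whose 33-class
   identity conflicts with the 5-class jaw/parity vote;
5. three backbone families are run as separate cascades and fused by
   **AdaBoost-weighted soft voting**: each model's vote weight is
   `alpha = 0.5 * log((1 - eps) / eps)` from its calibration error rate.

Because no clinical scans ship with the package, a **synthetic phantom
generator** supplies paired volumes and exact ground truth, and every
downstream claim in the test suite is made against phantoms.

## The phantom generator

Structures are analytic solids rasterized onto the voxel grid: an
ellipsoidal soft-tissue envelope, an ellipsoidal-shell cranial cap, an
elliptical-arc mandibular tube, a bulged vertebral column, a thin hyoid
arc, an air-filled pharyngeal tube, bilateral thin nerve canals inset into
the mandibular arch, and up to 32 teeth as capped columns placed along two
elliptical dental arches in FDI order. Default geometry is tuned for a
64-voxel cube at 1 mm isotropic spacing and scales proportionally with the
grid.

Intensities are CT-like conventions, not claims: air −1000/−900, soft
tissue ≈ 40, bone ≈ 700, teeth ≈ 1200, bracket metal ≈ 3000, plus Gaussian
noise with σ = 30 by default. What matters for a segmenter is the contrast
*ordering*, which these values preserve. Two deliberate difficulty
features are kept: the hyoid and the nerve canals are at most ~2 voxels in
radius, so the well-known difficulty of thin tubular structures is
reproducible here (and visible in the test results — the nerve canal is
consistently the worst class). Optional artifacts attach a metal bracket
blob to each tooth's buccal face with radial streaks.

What the phantom does **not** emulate: anatomical shape variation,
scanner physics beyond the streak heuristic, contact between adjacent
teeth, root geometry, or pathology. Passing tests therefore demonstrate
that the pipeline's machinery is correct and that its components behave as
designed — not that clinical-grade accuracy would be reached on real
scans.

Generation is a pure function of `(spec, seed)`: two calls with the same
arguments are bitwise identical. Two structure classes are intentionally
not single connected components: the nerve canal (bilateral, two
components) and the tooth foreground classes (one component per tooth).

## Backbone families

Three scaled volumetric encoder–decoder families stand behind one
prediction contract:

* `residual_unet` — residual double-conv blocks per stage;
* `dynamic_unet` — plain double-conv stages, with the per-level channel
  rule "halve spatial, double channels, capped at 8× base width";
* `large_kernel_unet` — depthwise large-kernel spatial mixing (default
  k = 5, configurable ≥ 5 odd) with pointwise channel mixing and a
  residual join.

These are desk-scale analogues: the point of the package is the
cascade/ensemble machinery, not backbone fidelity, and no self-configuring
planner or pretrained weights are involved. The networks and their
backpropagation are implemented in the package itself (C++ kernels for the
convolutions via blocked im2col + BLAS; analytic gradients are verified
against finite differences in the test suite).

Two design choices deserve emphasis:

* **Coordinate-augmented stem.** The input is the per-volume z-scored
  intensity plus three voxel-coordinate channels normalized to [−1, 1]
  over the full grid. Several CMF structures share CT intensity (skull,
  mandible, vertebra, hyoid are all bone) and are distinguished mainly by
  position; coordinate channels hand every patch its global location, a
  standard CoordConv-style device. `inChannels` in the configuration
  still counts image channels (1).
* **Full-resolution input skip to the heads.** The per-class 1×1 heads
  read the trunk's finest features concatenated with the raw input
  channels. A per-voxel rule on intensity and position is then always
  expressible by the head alone, which removes an initialization
  fragility we observed at desk scale: without the skip, whole
  structures could collapse into a neighbouring class early in training
  and never recover (the Dice term's gradient vanishes through the
  softmax for never-predicted classes).
* **Normalization default "none".** Inputs are already z-scored per
  volume and the phantom task is driven by absolute intensity and
  position; instance normalization (available as an option) washes out
  part of the intensity cue per patch and was slower to converge in our
  experiments, so the default is no normalization.

Inference uses sliding windows whose blending weights are accumulated and
normalized so they sum to 1 at every voxel, followed by renormalization of
each per-voxel class vector onto the simplex (tolerance 1e-6). Argmax ties
take the lowest class id, everywhere.

## Training

The published loss surface of the package is pure soft Dice:
`softDiceLoss` (background excluded from the class mean by default,
smoothing constant 1e-5) and `fineLoss`, the dual-head combination with
weights `lambda1 = lambda2 = 0.5` by default (the weights are exposed in
`fineLossConfig` and the pipeline configuration; no published values exist
for them, so an equal split is the neutral default).

The training *objective* adds an auxiliary voxel-wise cross-entropy term
(weight `ceWeight`, default 1) with median-frequency class balancing
(clipped at 20×). Dice + CE is the conventional combination for
optimizing volumetric U-Nets; the Dice term alone propagates vanishing
gradients through the softmax for classes the model does not yet predict,
which stalls small structures. Setting `ceWeight = 0` recovers pure Dice
training.

The optimizer default is Adam (lr 0.003–0.006 works well at these scales);
plain SGD with momentum 0.9 remains available as `optimizer = "sgd"`.
Patches are drawn uniformly per sample each epoch; a class-balanced
sampling mode (half the patches centred on random foreground voxels) is
available but off by default — combined with the balanced cross-entropy
term it over-weights minority structures and slowed convergence of the
large classes in our experiments. Training is deterministic
end-to-end given the seed: identical seeds give identical histories and
weights.

`kfoldSplit` provides deterministic k-fold cross-validation splitting
(default k = 5), with validation sets partitioning the ids and sizes
differing by at most one.

## Cascade details and numerical conventions

* Voxel indices are 0-based, axis order (x, y, z) with x left–right,
  y anterior→posterior, z inferior→superior; all boxes are half-open
  `[lower, upper)`.
* The dentition ROI is the tight box of coarse ids 8/9 dilated by
  `roiMargin` (default 3 voxels — no published value exists) and clipped
  to the grid. One box covers both arches; an empty dentition falls back
  to a whole-volume ROI, flagged on the result.
* `cropResample` uses centre-aligned resampling: output voxel `v` samples
  input coordinate `lower + (v + 0.5) * scale − 0.5`. Labels always use
  nearest neighbour (label-set closure); images default to trilinear with
  nearest available as an option, since the source text describes nearest
  neighbour for both. The affine is updated so world coordinates remain
  exact; with no resampling, crop→paste is the identity inside the box.
* The fine-stage ROI target is a 64³ grid by default
  (`fineTargetShape`).
* Stage disagreement (fine tooth voxels outside the coarse tooth
  foreground) is recorded as a diagnostic, never enforced away.

### Combination correction

The source text motivates a "combination forecasting" correction from the
features of adjacent teeth but gives no algorithm, so the operational rule
here is a documented interpretation, applied at the level of connected
components of the 33-class argmax:

1. components are processed in descending size;
2. a component's parity vote is the modal nonbackground 5-class argmax
   over its voxels, and its confidence the mean voted-class probability;
3. a parity-consistent component is never changed;
4. an inconsistent component with confidence ≥ τ (default 0.6) is
   relabeled to the id that (a) stays in the component's current arch
   side — parity misidentification is an adjacent-tooth, same-side
   phenomenon, (b) matches the voted jaw/parity group, and (c) preserves
   within-quadrant ordering against already-accepted components, using the
   anterior–posterior centroid coordinate, which grows monotonically from
   incisors to molars along an arch quadrant; among admissible candidates
   the summed 33-class probability decides, ties to the lowest id. If no
   candidate satisfies the constraints the component keeps its id.

The rule is idempotent on consistent inputs and is exercised by planted
misidentification fixtures with a unique correct answer.

## Ensemble

Fusion is **soft** voting: `fused(v, c) = Σ_t w_t p_t(v, c)` with
`w = alpha / Σ alpha` (uniform if all `alpha` are zero). Soft voting is
strictly more informative than hard voting and reduces ties; it degrades
gracefully to the hard-voting result as predictions sharpen.

Calibration interprets boosting at the **sample (scan) level**: the
misclassification unit is a whole calibration sample, "misclassified" when
its mean foreground Dice falls below `D*` (default 0.95). Error rates are
clipped to `[1e-4, 0.5]` so that `alpha ≥ 0` — a worse-than-chance model
gets zero vote rather than a negative one. Models are processed in a
fixed, documented order (descending unweighted mean Dice); sample weights
start uniform, are multiplied by `exp(alpha_t)` on misclassified samples
and renormalized. The boosting pass is calibration-only: sample weights
are not fed back into retraining. Coarse and fine stages can carry
separate weight sets (`runELSeg(fineWeights=)`); the fine ROI used for
fusion is the union of the three cascades' boxes, resampled once to a
common grid.

## Evaluation

Dice `2|A∩B|/(|A|+|B|)` and IoU `|A∩B|/|A∪B|` use the standard
set-overlap definitions; rows satisfy `Dice = 2·IoU/(1+IoU)` to 1e-12.
When a class is absent from both maps the score is **not applicable**
(NA), excluded from aggregation — silently scoring 1 would inflate means
on missing teeth, and scoring 0 would punish nothing. Surface deviation
takes each mask minus its 6-neighbourhood erosion as the surface, computes
all-pairs minimum distances in both directions in mm, and reports the mean
and maximum; distances scale linearly with spacing.

`compareGroups` assesses normality per group (Shapiro–Wilk at 0.05, a
design decision), then runs a two-sample t-test when both groups pass and
the Mann–Whitney U test otherwise; zero-variance input falls back to the
rank test. `gradeReport` encodes the four-grade rubric: per-category
grades from Dice cut-offs (defaults A ≥ 0.95, B ≥ 0.90, C ≥ 0.80, else D —
an automated proxy for human grading, labeled as such), and an overall
grade that is "A" only if every category is "A", otherwise the worst
category grade.

## Problem sizes used by the tests and the acceptance script

All sizes are the package's own choices for a desk-scale study: phantoms
are 64³ (48³ for geometry-only checks); the end-to-end recovery study
trains the three families (depth 3, width 8) on 20 phantoms and evaluates
on 5 held-out phantoms; the noisy-oracle ensemble study uses 10 phantoms
at 48³ with voxel error rates 0.10/0.20/0.30; the parity-correction study
uses 100 constructed fixtures; metric-oracle equivalence uses 1,000 random
8³ label pairs. Seeds are pinned throughout.

## Known limitations

* At the study budgets above, the fine 33-class stage is deliberately
  under-trained (about 120 gradient steps): its tooth Dice is low and
  still rising when training stops. The end-to-end study's claims concern
  the coarse stage and the ensemble gain; longer fine-stage schedules
  improve tooth Dice steadily but are outside the desk-scale budget.
* The backbone analogues are small; their absolute accuracy ceilings are
  set by the phantom's simplicity and say nothing numeric about clinical
  data.
* The nerve canal (thin, tubular) is consistently the hardest class, by
  design.
* The correction rule assumes arch-side stability of misidentifications
  and anterior–posterior ordering within quadrants; dentitions with
  transposed or ectopic teeth violate those assumptions.
* Boosting weights are calibrated at the scan level; per-structure or
  per-voxel weighting is out of scope.
* DICOM ingestion, mesh export and human grading workflows are out of
  scope.
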