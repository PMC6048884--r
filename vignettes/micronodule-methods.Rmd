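---
title: "Methods: micro-nodule versus non-nodule classification from CT patches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: micro-nodule versus non-nodule classification from CT patches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Automated lung-nodule detection pipelines screen CT volumes with permissive
intensity and morphology thresholds and then reclassify the resulting
candidates to suppress false positives. For micro-nodules — lesions under
3 mm in diameter — this second stage is especially hard: at typical in-plane
spacings a micro-nodule spans only a few pixels, and vessels seen in cross
section look very similar. `micronodule` implements a patch-based
false-positive-reduction stage for this regime: small square intensity
windows centred on annotated candidate points are classified as
micro-nodule (label 1) or non-nodule (label 0) by compact convolutional
networks, and the comparison of interest is how network depth (1, 2 or 4
convolutional layers) and receptive field (16, 32 or 64 pixels) drive
performance.

## Annotation model

The package reads the annotation dialect used by large public lung-CT
archives: one XML document per scan, up to four reading sessions (one per
expert; only final, unblinded reads are served), and within each session
lesion elements of two syntactic kinds. Nodule elements carry one or more
ROIs of edge-map points; non-nodule elements carry a single "Locus" point.
The lesion taxonomy is derived from this syntax:

* **nodule** (3–30 mm): an element with a closed contour of at least three
  edge points. Parsed for completeness, but it produces no patches.
* **micro-nodule** (< 3 mm): a nodule element whose ROI set reduces to a
  single distinct point — these lesions have no contour, only a
  three-dimensional centre of mass.
* **non-nodule**: a locus-bearing element, likewise a single point.

Marks from different readers are deliberately *not* merged: each reader's
mark yields its own patch. Concordant readers therefore contribute
near-duplicate patches, which matches the scale of the reported archive
totals (tens of thousands of patches from roughly a thousand scans) and is
the protocol evaluated here.

Duplicate scans are removed before extraction. Since the archive names no
duplicate identifiers, the only scan-intrinsic criterion is content
equality: each scan is fingerprinted by a hash of its sorted slice-UID set,
and within a fingerprint group the scan with the lexicographically smallest
patient-id + fingerprint key survives.

A lesion element with neither edge points nor a locus is recorded as a
mark-level error; the scan as a whole is still returned, so one malformed
mark cannot discard an annotated scan.

## Patch extraction

CT series are loaded from DICOM slices (sorted by ascending axial position,
stored values converted to Hounsfield units through each slice's rescale
slope and intercept). Because no DICOM reader is available in this
package's dependency set, `micronodule` ships a deliberately narrow
explicit-VR little-endian reader/writer covering exactly the identifier,
geometry, rescale and pixel tags the pipeline touches; the synthetic
fixture generator emits the same dialect.

Extraction conventions, chosen once and recorded so stored patches are
reproducible:

* Annotation x/y are treated as 0-based column/row indices (x is the
  column axis). The manifest records the resolved voxel per patch so a
  ±1 audit against any other convention is possible.
* Slices resolve by exact SOP-UID match first, otherwise by nearest slice
  z within half the median slice spacing; anything farther is a skip,
  logged with its reason.
* An even-sized window is centred with the half-open convention
  `[c - s/2, c + s/2)`, putting the mark at patch pixel `(s/2 + 1, s/2 + 1)`.
  This makes the 16-pixel window an exact sub-array of the 32, and the 32
  of the 64 — a property the tests check bit-exactly.
* Positions outside the image are filled with −1000 HU (air) rather than
  shifting the window; shifting would de-centre the lesion.
* Intensities are clipped to the standard lung window [−1000, 400] HU and
  mapped affinely to [0, 1]; a fixed window keeps the mapping
  scan-independent.

## The three networks

All three architectures operate on single-channel (grayscale) patches and
end in a two-unit softmax:

| model | stack |
|---|---|
| M1 | conv 32@3×3 → maxpool → dense 256 → dropout 0.5 → dense 2 → softmax |
| M2 | conv 64@7×7 → ReLU → maxpool → conv 128@2×2 → dropout 0.5 → dense 256 → dense 2 → softmax |
| M3 | conv 32@3×3 → maxpool → conv 64@3×3 → maxpool → conv 128@3×3 → maxpool → conv 256@2×2 → dropout 0.5 → dense 256 → dense 2 → softmax |

The fixed points of the design are the depth progression 1/2/4, M1's 3×3
kernel and M2's kernel complement — 64 filters of 7×7, then 128 of 2×2,
the small-kernel choice that lets the second layer pick up fine detail in
lesions only a few pixels wide. The remaining hyperparameters are package
defaults, surfaced through the layer helpers so sensitivity can be
explored: M1/M3 filter counts (32 and 32/64/128/256), dense width 256,
dropout rate 0.5, all poolings 2×2 with stride 2, and valid (unpadded)
convolutions throughout.

Two geometry consequences of valid padding are worth stating explicitly.
First, M3 cannot accept 16-pixel input: after its three poolings the
feature map collapses below the next kernel, and `build_m3(16)` (and the
corresponding experiment-matrix cell) fails with a shape error naming the
offending layer rather than silently padding. Second, M3's fourth
convolution uses a 2×2 kernel: with a 3×3 kernel the 32-pixel input — the
patch size at which all three models are meant to be compared — would
itself collapse (…→ 2×2 before the fourth conv). Shrinking the final
kernel to 2×2 follows the same fine-detail reasoning that fixes M2's
second-layer kernels at 2×2, and keeps M3's conv/pool interleaving intact.
M1 carries no explicit activation layer; its conv-plus-dense stack is
therefore linear, which is part of why depth matters in the comparison.

`propagate_shapes()` applies the valid-padding arithmetic
`n' = floor((n − k)/s) + 1` layer by layer and fails on any non-positive
dimension; parameter counts are the usual `k_h k_w C_in C_out + C_out` for
convolutions and `n_in n_out + n_out` for dense layers. The tests verify
both against an independent brute-force oracle for all nine model × size
combinations.

## Training

The optimizer is plain SGD with momentum. Defaults: learning rate 0.0001,
momentum 0.9, 50 epochs (120 for M2, the deeper run its slower convergence
rewards), two-class softmax cross-entropy, batch size 128. An epoch is one
full pass with a seeded reshuffle, and per-iteration batch loss and
accuracy are recorded as the training history.

Further fixed choices:

* **Initialization** — variance-scaling uniform with He scaling
  (`U[±sqrt(6/fan_in)]`), the standard scheme for rectifier networks,
  biases zero, drawn from R's RNG under the configured seed.
* **Input normalization** — the training-set mean intensity is subtracted
  before training and stored in the fit, mirroring the zero-centre input
  default of mainstream training frameworks. At a learning rate of 0.0001
  this matters: on all-positive `[0, 1]` inputs the softmax calibrates far
  too slowly for short runs, while ranking (AUC) is largely unaffected.
* **Numerics** — the engine (im2col convolution, pooling, dense, inverted
  dropout, softmax cross-entropy, SGD with momentum) is compiled C++ in
  single precision over BLAS matrix multiplies. All stochastic elements
  (initialization, epoch shuffles, dropout masks) draw from R's RNG, so a
  fit is exactly reproducible from its seed on a given platform.
  Backpropagation is verified against central finite differences, and a
  dense-softmax-only network is checked against `glm()` logistic
  regression.

## Cross-validation and metrics

`make_folds()` builds five disjoint, exhaustive folds whose sizes differ by
at most one, stratified so each fold's label ratio matches the global ratio
to within one item per class (within each class, indices are shuffled once
and dealt cyclically, with the dealing position carried across classes).
`run_cv()` trains on four folds and scores the fifth, so every patch is
scored exactly once; per-fold metrics, their unweighted mean (the headline
aggregate) and pooled-prediction metrics (for audit) are all returned.
Splits are at patch level, not patient level, matching the evaluated
protocol; because multiple readers mark the same lesions, patch-level
splitting is optimistic about generalization to new patients, and the
result object says so.

Metrics treat class 1 (micro-nodule) as positive:

* the **average F-score** is the sum over both classes of
  `P·R/(P + R)` — each term is half the class F1, so for two classes the
  sum equals the macro-averaged F1 (the tests verify this identity over
  1000 random tables to 1e−12);
* **accuracy** is the correctly classified fraction; **sensitivity** is
  class-1 recall;
* the **ROC/AUC** sweeps unique scores as thresholds (ties advance
  jointly) and integrates trapezoidally, which equals Mann–Whitney pair
  counting with half credit for tied pairs (also verified to 1e−12);
* a score exactly at the 0.5 decision threshold predicts class 1, and a
  zero-denominator precision or recall contributes 0 rather than NaN, so
  degenerate CV folds stay well defined.

All metrics are fractions in [0, 1]; results tables multiply by 100 and
label columns `F-score (%) / Accuracy (%) / Sensitivity (%) / AUC (%)`.

## Synthetic fixtures

Two generators make the pipeline testable without any archive download.

`generate_scan_fixture()` writes a miniature DICOM series plus a
matching annotation XML from a plan of planted marks, covering every parser
branch: single-point nodule elements (micro-nodules), locus elements
(non-nodules), polygonal contours (nodules), empty reading sessions, and
duplicated scans sharing slice UIDs.

`generate_patch_dataset()` emits labelled patches: class 1 carries a
centred Gaussian blob whose diameter is drawn in [1, 2.9] mm-equivalents at
0.7 mm nominal spacing (honouring the < 3 mm definition); class 0 carries a
vessel-like ridge whose perpendicular distance from the centre is at least
a quarter of the patch side. Both sit on correlated background texture
(smoothed white noise, variance-normalized) and both structure amplitudes
equal `separation × noise_sd`, so at `separation = 0` the two class
distributions are identical by construction — the permutation-style null
the tests rely on. The defaults (`separation = 5`, `noise_sd = 0.08`) give
clearly learnable classes.

What the generator does *not* emulate: real CT noise spectra, partial
volume effects, juxta-pleural context, reader disagreement structure, or
the archive's class imbalance. Passing tests therefore demonstrate that
the pipeline's mechanics — parsing, geometry, bookkeeping, optimization,
evaluation — are correct, not that the headline archive-scale accuracies
transfer.

## Problem sizes used by the checks

The test-suite and acceptance-script experiments use desk-scale sizes
chosen to exercise the full protocol while staying quick on one CPU: the
learnability check trains M2 for 20 epochs on 1600 of 2000 synthetic
32×32 patches (batch 128, lr 0.0001, momentum 0.9) and evaluates on the
held-out 400, once with true and once with permuted labels; the metric
identities use 1000 random instances each; the extraction round trip uses
a 64×64×3 volume with 9 planted marks across 3 readers. Archive-scale
quantities — patch totals in the tens of thousands and cross-validated
performance over the full 3 × 3 experiment matrix on real data — require
the external archive and nine long trainings, and are out of desk-scale
scope by design.

## Known limitations

* The DICOM reader is minimal by design: explicit-VR little endian only,
  no sequences, no compressed transfer syntaxes. Real archive data in
  other syntaxes must be converted before loading.
* Single-precision training is exactly reproducible on a given
  platform/BLAS, but bit-level results can differ across BLAS builds.
* Patch-level CV leaks patient context across folds (documented above).
* The micro-nodule rule (single distinct point) relies on the annotation
  dialect's convention; an archive variant that contours micro-nodules
  would classify them as nodules and drop them from extraction.
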