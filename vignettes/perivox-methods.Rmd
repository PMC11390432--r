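---
title: "Segmenting and counting perivascular spaces: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting and counting perivascular spaces: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perivox)
```

## The problem

Perivascular spaces (PVS, Virchow-Robin spaces) are fluid-filled sheaths
around small penetrating vessels. On axial T2-weighted MRI they are
CSF-bright and very small: a vessel running in the scan plane appears as a
thin line, a vessel crossing the plane as a dot of one or a few voxels.
Clinical assessment still relies on visual counting on anatomically
selected slices, which is slow and rater-dependent. `perivox` implements a
supervised segmentation pipeline for whole-volume PVS masks on 3T axial
T2 images, voxel-overlap evaluation, and the slice-based counting workflow
used to compare automated output against raters.

The package is organised in the classical modelling idiom: `train_model()`
is the fitting function and returns a classed `pvs_fit` with `print`,
`summary`, `plot` and checkpoint accessors; `predict()` on the selected
`pvs_net` produces a binary mask volume. Everything else (phantom
simulation, fold construction, evaluation, counting) are plain functions
around that core.

## The segmentation model

The network is a densely nested encoder-decoder: a triangular grid of
convolutional nodes `X(i, j)` with `i` the resolution row (0 = finest) and
`j` the position along the skip pathway. Column `j = 0` is a plain
encoder (each node consumes the 2x2 max-pooled output of the row above);
every nested node `X(i, j > 0)` consumes the concatenation of all same-row
predecessors `X(i, 0..j-1)` and the bilinearly upsampled, 1x1-projected
output of `X(i+1, j-1)`. Each node is two 3x3 convolution + batch-norm +
ReLU blocks with an optional squeeze-and-excite channel-attention gate.
Each decoder row ends in a 1x1 convolution + sigmoid head at its native
scale, so a forward pass emits an `L`-level probability pyramid. The
rationale for nesting is receptive-field matching: sub-networks of
different depth are best suited to targets of different sizes, and for
structures as small as PVSs the shallow, fine-scale paths must not be
forced through a deep bottleneck.

Deep supervision uses *foreground-preserving label pyramids*: the ground
truth is downsampled by repeated 2x2 max-pooling, so a coarse label pixel
is foreground iff any pixel of its fine-scale block is. Under
average-pooling a one-voxel PVS fades to a small fraction after two
levels and effectively disappears from the coarse losses; under max
pooling it survives to every supervision depth. An average-pool soft-label
variant is available (`hf_downsample(..., policy = "mean")`) for
comparison.

Each head is scored with the soft dice loss

$$\ell(p, y) = 1 - \frac{2\sum p y + s}{\sum p + \sum y + s},$$

with stabiliser `s = 1` by default, and the multi-scale loss is the
(uniformly) weighted mean over heads. As `s` tends to 0 on binarised
predictions, `1 - loss` recovers the evaluation DSC exactly; the test
suite checks this at `s = 1e-6` to a tolerance of `1e-4`. Empty-vs-empty
slices score a loss of 0 (agreement on absence), which keeps all-background
slices usable in training.

Training follows the reference protocol: mini-batches of 4 axial slices,
Adagrad at learning rate 0.05, up to 1000 epochs with the epoch-50
checkpoint deployed. Checkpoint selection is deliberately *fixed-epoch*,
not best-validation; a `best_val` policy is provided as an alternative.
Inference binarises the finest head at a strict threshold of 0.5
(a probability exactly at the threshold stays background, which makes
binarisation bit-reproducible); optional head fusion by averaging is
behind a flag.

### Design choices where the architecture was genuinely open

* **Node wiring** follows the densely nested (UNet++-style) topology —
  the closest published match to a "densely nested" grid of
  interconnected nodes. Down/up transitions are 2x2 max-pool and bilinear
  upsampling + 1x1 projection, the standard small-object-preserving pair;
  strided or transposed convolutions would discard or invent sub-voxel
  structure.
* **Attention** is per-node channel attention (squeeze-and-excite:
  global average pool, a two-layer gate MLP, sigmoid channel scaling),
  toggleable so its effect is measurable. The gate's hidden layer uses a
  leaky activation (slope 0.1): at the small gate widths this package
  uses, a hard ReLU frequently leaves a whole gate dead and its
  parameters without gradient.
* **Widths** default to 32 channels on the finest row, doubling per row.
* **Normalisation** is batch-norm with the training batch statistics
  (momentum 0.1, eps 1e-5), configurable to none.
* **Implementation**: the forward/backward passes are written in R with
  Rcpp kernels for patch extraction (im2col/col2im), pooling, bilinear
  resampling and connected-component labelling; all dense algebra goes
  through BLAS. Gradients are exact — the suite checks every parameter
  class against central finite differences at `1e-5` relative tolerance.

## Preprocessing and geometry

Volumes are z-score normalised per volume (mean 0, variance 1), the
minimal scanner-scale removal; no registration, bias-field correction or
skull stripping is performed. Slices are zero-padded symmetrically to a
side multiple of `2^(L-1)` — padding, never resizing, because
interpolation would blur exactly the thin structures of interest. The
padding geometry is recorded and inverted exactly on reassembly.
Coordinates are 0-based slice indices along z; slice thickness is read
from the NIfTI header.

## Cross-validation protocol

Subjects are sorted by age and dealt round-robin into five folds, which
bounds the fold-mean age deviation by `range * k / n` (asserted as a
property test). Per round one fold is the test set, one seeded draw among
the remaining folds is the validation set, and the other three train the
model; across rounds every subject is tested exactly once. Whether the
validation fold should be re-drawn per round was an open choice; it is
re-drawn from the seeded stream. Fold construction, weight
initialisation and batch order all derive from the configured seed, so a
run is exactly reproducible.

## Evaluation

Voxel metrics are `DSC = 2TP/(2TP+FP+FN)`, `SEN = TP/(TP+FN)` and
`PPV = TP/(TP+FP)`, computed over whole volumes (the natural reading of
per-subject scores). `0/0` cases are scored 1 when both masks are empty
and 0 otherwise, flagged `degenerate`, and excludable from aggregation.
Aggregation reports the arithmetic mean and the *population* standard
deviation (divisor `N`): this is the convention under which the bundled
benchmark table's printed Std row is reproduced exactly (the sample
convention gives 0.026 where 0.025 is printed). Rounding to 3 decimals
happens only at display. The bundled fixture
(`benchmark_scores()`) carries the per-subject DSC/SEN/PPV of five
models on a 20-subject Parkinson's disease cohort; the imaging data
themselves are not redistributable, so the fixture is the regression
anchor for aggregation and reporting.

## Burden counting

Raters count PVSs on two anatomically selected axial slices: basal
ganglia on the anterior-commissure slice, centrum semiovale 1 cm above
the uppermost slice of the lateral ventricles (`ceiling(10 mm / slice
thickness)` slices up; 5 slices at 2 mm). Counts are connected
components of the binary slice under 8-connectivity — a thin oblique PVS
whose pixels touch diagonally is one structure, not two; 4-connectivity
and a minimum-area filter are exposed but off by default. How a rater
counts a long tube crossing a slice obliquely is not fully specified by
any protocol; connected components is the implemented proxy. Agreement
uses tie-corrected Spearman correlation with an exact permutation
p-value for `n <= 8` and the t approximation above.

## The phantom generator

Real cohort data cannot ship with the package, so every stage is
exercised on a synthetic phantom whose geometry mirrors the target data:
anisotropic voxels of 0.69 x 0.69 x 2.00 mm, a 320 x 320 in-plane matrix
by default, an ellipsoidal "brain" at a uniform tissue intensity with a
central CSF-bright ventricle block, and PVSs as CSF-bright capsules —
in-plane segments (lines on axial slices) and through-plane segments
(dots). Confounders mirror the reported failure modes of PVS segmenters:
curvilinear bright arcs hugging the brain boundary (sulci mistaken for
PVSs), larger bright blobs (lacunes), and a configurable fraction of
low-contrast PVSs (faint PVSs are the canonical miss). Rician noise
(magnitude of a complex Gaussian signal) is the default, with a Gaussian
option for analytic convenience.

Deliberate choices and limits:

* The anatomy is schematic — ellipsoid plus ventricle block — because
  only the slice-selection landmarks need emulating, not cortical
  anatomy. No k-space simulation, bias field or partial-volume model is
  attempted; a passing pipeline on phantoms demonstrates mechanical
  correctness and the expected orderings (clean easier than confounded),
  not clinical-grade accuracy on real MRI.
* Capsule rasterisation always paints at least the centre voxel, so a
  requested structure cannot vanish when its radius is below the voxel
  size; requested counts survive anisotropic sampling.
* Structure placement enforces a minimum centre and surface separation,
  so ground-truth component counts equal structure counts by
  construction; per-slice truth counts are nevertheless recomputed from
  the mask by connected components and cross-checked against an
  independent flood fill in the tests.
* Intensities are arbitrary units with `pvs ≈ csf > tissue`; no
  quantitative PVS size/contrast distribution for a real cohort is
  published, so defaults (radius 0.35-1 mm, tubes 5-25 mm) are chosen
  for testability, not epidemiological realism.
* Subject `k` of a dataset derives its seed as `seed + k - 1`, so a
  dataset can be extended without reshuffling earlier subjects; ages are
  drawn uniformly on 42-79 years, the typical span of a Parkinson's
  disease cohort, so fold balancing has realistic input.

## Problem sizes used in tests and the acceptance script

Training a full-resolution network on a 20-subject cohort is a GPU-scale
job and the cohort is not distributable, so the package's end-to-end
checks run a scaled-down surrogate chosen to finish on a single CPU: 5
phantom subjects of 64 x 64 x 16 voxels, a depth-3 network with 8 base
channels, batches of 4, Adagrad at 0.05, 15 epochs per fold. Under these
conditions held-out mean DSC on clean, high-contrast phantoms is
required to reach at least 0.5, and the same pipeline on phantoms with
sulcus/lacune confounders and 30% low-signal PVSs must score strictly
lower — an ordering the failure-mode design of the generator predicts.
The full-scale benchmark mean DSC of 0.702 on real patients is *not*
reproducible at this scale; the fixture regression plus the surrogate
ordering are the substituted evidence.

## Known limitations

* 2D slice-wise segmentation only; no 3D convolutional variant (axial
  anisotropy with 2 mm slices makes through-plane continuity weak).
* No pretrained weights; every run trains from scratch.
* Landmark slices (anterior commissure, ventricle top) are inputs on
  real data; the package does not detect them.
* The R/Rcpp training loop is single-threaded BLAS-bound; it is sized
  for method validation and small studies, not for large-cohort
  training.
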