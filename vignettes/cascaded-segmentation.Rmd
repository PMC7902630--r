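---
title: "Auto-context cascaded orthogonal-plane segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auto-context cascaded orthogonal-plane segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Small bright anatomical structures in volumetric CT — the inner-ear bony
labyrinth in micro-CT is the motivating case — are hard to segment slice by
slice: on any single 2D plane, pneumatized air cells and other cavities look
locally identical to cochlear or canal lumina, and purely intensity-based
rules commit false positives on many slices. Full 3D networks would resolve
the ambiguity but are expensive at volume sizes of 256^3 and need more
annotated volumes than such datasets typically contain (each volume is one
training case for a 3D model, but hundreds of slices for a 2D one).

`cascadeseg` implements a middle road: a three-stage *auto-context* cascade
of 2D encoder-decoder networks operating on the three orthogonal anatomical
planes, with a 3D largest-connected-component refinement between stages.

## The cascade

Stage $s \in \{1,2,3\}$ slices the volume along one anatomical axis
(default order: coronal, sagittal, axial) and feeds each slice to a 2D
network with $s$ input channels: the image slice plus the binary masks
produced by all previous stages, resliced along the current axis. Each
stage's per-slice probability maps are reassembled into a 3D volume,
binarised (voxel foreground iff probability strictly exceeds 0.5), and
reduced to the largest 3D connected component. The third stage's mask is
the system output, so the output always has at most one component.

The two mechanisms complement each other:

* the largest-component step removes predictions that are disconnected in
  3D — exactly the air-cell type of error a 2D slice classifier makes;
* the prior-mask channels let later stages see, on their own slicing plane,
  a cross-section of what the earlier stages (working on *other* planes)
  considered foreground — injecting 3D context into 2D classifiers.

The final output's connectivity contract (at most one 26-connected
component) holds by construction, regardless of network quality.

### Stage networks

All three architectures share the encoder-decoder skeleton: `depth`
repetitions of [two (3x3 conv, batch norm, ReLU) layers, then 2x2 max
pooling] with filter counts doubling per level from `base_filters`; a
bottleneck block with dropout (rate 0.2); a mirrored decoder using stride-2
transposed convolutions (kernel 2) and skip concatenation in channel order
[upsampled, skip]; and a 1x1 convolution with sigmoid head.

* **unet** — exactly the skeleton above.
* **resunet** — each double-conv block becomes a residual block: the 3x3
  path (conv-BN-ReLU, conv-BN) summed with a parallel 1x1 projection of the
  block input, then ReLU.
* **seunet** — each block is followed by squeeze-and-excitation channel
  recalibration (global average pool, bottleneck MLP with reduction ratio
  `se_ratio`, sigmoid gate). The same ratio (default 8) is used at every
  level; when a block has fewer channels than the ratio the bottleneck
  width floors at 1.

Convolutions use zero-padded "same" borders so output size equals input
size. Batch normalisation uses momentum 0.9 and epsilon 1e-3 (this
engine's defaults, recorded in the model config). Weight initialisation is
He-normal, fully determined by the seed; the head bias starts at -2 so an
untrained network predicts background everywhere — the standard
background-prior initialisation for dense prediction with a rare
foreground class, which stabilises the first training epochs.

The engine is self-contained: convolution, pooling and transposed
convolution run as compiled im2col/GEMM kernels in single precision (the
standard precision for network training), everything else in R. Gradients
of every layer are validated in the test suite against an independently
written double-precision reference network at tolerance 1e-3, and the
whole loss agrees with that reference to 1e-5.

### Training protocol

Stages train strictly sequentially with Adam on mean per-voxel binary cross
entropy, shuffled mini-batches (default size 20), up to `max_epochs` with
early stopping on the *training* loss; the checkpoint with the lowest
training loss is kept. Checkpointing on training rather than validation
loss is a deliberate protocol choice of this pipeline (the cross-validation
harness keeps the held-out fold completely untouched); the usual caveat
about overfitting long schedules applies, and dropout in the bottleneck is
the counterweight.

Stage $s > 1$ training inputs use the *post-processed predictions* of the
already-trained stages on the training volumes — not the ground-truth
masks — as prior channels. Training on ground-truth priors would present
later stages with a cleaner prior distribution than they will ever see at
inference time; using predecessor predictions keeps the train and test
input distributions identical.

An empty intermediate mask (a stage that predicts nothing) is passed on as
an all-zero prior channel with a warning rather than aborting: a total miss
at stage 1 can still be recovered by later stages that see the image.

## Data handling

Volumes are 3D grids with per-axis mm spacing and an explicit mapping of
grid axes to the anatomical directions (axial / coronal / sagittal), read
from NIfTI or NRRD headers; when a file carries no usable orientation the
caller must name the axes — they are never guessed. NIfTI-1 stores spacing
as 32-bit floats, so spacing round-trips at float precision there and
exactly through NRRD.

Resampling to a fixed cube (the pipeline's working resolution) preserves
each axis's physical extent: `spacing_out = spacing_in * dim_in / size`.
Images use a separable natural cubic spline (orders 0 and 1 are available;
quadratic and quartic/quintic spline orders are not implemented, as no
interpolation machinery for them exists in the R ecosystem and the
pipeline has no use for them). Label masks always resample
nearest-neighbour: spline weights would produce non-binary label values, so
interpolation order is *not* a free parameter for labels.

Intensity normalisation (zero mean, unit standard deviation) is fitted by
pooling the voxels of the *training* volumes only — the fitting function
takes just the training list, so test leakage is impossible by
construction — and uses the population (divisor $n$) standard deviation.
Within cross-validation the normalizer is refitted per fold.

## The phantom generator

Real micro-CT specimens are large and externally hosted, so the package
ships a synthetic phantom family that reproduces the two properties the
cascade exploits, at desk scale (default 64^3 voxels, 0.15 mm spacing,
foreground around 1-2% of the grid):

* **a single connected bright target**: a helical cochlear tube whose
  spiral and tube radii taper over 2.5 turns, three partial-torus canal
  arcs in near-orthogonal planes, and a vestibule ellipsoid; every
  component is anchored to the vestibule, so the rasterised label is
  exactly one 26-connected component (verified sample by sample in tests).
  The whole labyrinth is rotated to an oblique orientation: the real
  cochlear and canal planes are oblique to all cardinal anatomical planes,
  and an axis-aligned spiral would hand one slicing orientation a
  privileged whole-structure view that real data does not provide
  (reported orientation differences are at the percent level);
* **disconnected confounders**: air-cell-like spherical blobs rendered at
  the same intensity as the target, placed by rejection sampling at a
  minimum distance from the label that exceeds the blur support, so they
  can never merge with the target; a midpoint intensity threshold provably
  commits false positives on some slices, i.e. the phantom actually poses
  the 2D confusion problem.

Bone is textured with band-passed Gaussian noise — only the intensity
confusability matters, not anatomical realism. Rendering applies Gaussian
blur (partial-volume effect) and additive Gaussian noise. Every sample is a
pure function of (spec, seed); dataset generation derives per-sample seeds
from one master seed and jitters the geometric parameters within ±10% so
specimens differ.

What the phantoms do *not* model: scala tympani/vestibuli substructure,
the modiolus and ossicles, scanner artefacts (beam hardening, rings),
anisotropic resolution, and misaligned ground truth. A cascade that
performs well on phantoms has demonstrated its plumbing, its learning
machinery and its robustness to disconnected confounders — not clinical
performance.

## Evaluation

Per volume, against ground truth Y with prediction X: Dice
$2|X \cap Y| / (|X| + |Y|)$, Jaccard, accuracy, precision, recall,
specificity, voxelwise ROC AUC, and the symmetric 3D Hausdorff distance in
mm over the full foreground voxel sets with anisotropic spacing honoured
(computed via an exact Euclidean distance transform; the test suite checks
it against the quadratic pair-loop oracle). Degenerate ratios (0/0) are
defined as 1 when both masks are empty and 0 otherwise, and flagged; an
empty mask makes the Hausdorff distance undefined and it is reported as
missing, never as 0. AUC uses the rank/Mann-Whitney identity with half
credit for ties, computed on the sigmoid probabilities (thresholded masks
would make the AUC uninformative), per volume and then averaged.

Paired model comparisons use the two-sided Wilcoxon signed-rank test with
zero differences dropped. For up to 25 pairs the p-value comes from the
exact null distribution computed by dynamic programming over doubled
ranks — valid under ties, where the textbook tables and
`stats::wilcox.test`'s exact path do not apply; above 25 a normal
approximation with tie correction is used. The test suite verifies
exactness against full enumeration of all $2^n$ sign assignments.

## Numerical and design choices

* Binarisation threshold 0.5 with a *strict* inequality; exact ties (e.g.
  a constant 0.5 map) yield background.
* Connected components default to 26-connectivity — the most permissive
  neighbourhood, least likely to sever the thin canal tubes; equal-size
  ties resolve to the component appearing first in grid scan order.
* `largest_component` of an empty mask is the empty mask plus a warning.
* Fold assignment shuffles specimens and deals them round-robin: fold
  sizes differ by at most one (17 specimens into 4 folds gives 5/4/4/4),
  and slices never cross folds because assignment happens at specimen
  level.
* All randomness flows through explicit integer seeds; child seeds are
  derived deterministically, RNG state is restored after every seeded
  operation, and repeated runs are bit-identical.

## The desk-scale benchmark

The acceptance benchmark (also available as `scripts/acceptance.R`) trains
tiny networks — depth 2, 8 base filters, 64x64 slices — on 8 phantoms (6
train / 2 test). At this scale the networks converge in a handful of
epochs, so the benchmark uses Adam at learning rate 2e-2 (the production
default of 1e-4 suits the full 256-resolution setting and long schedules)
with batch size 20: 4 epochs per stage on clean phantoms, where the
trained cascade reaches a training Dice above 0.8, and 5 epochs per
network — the same budget for every network of both systems — in the
single-orientation baseline comparison on confounder-bearing phantoms.
Problem sizes were chosen so the whole benchmark, including phantom
synthesis and evaluation, completes in minutes on one CPU core.

Two properties are asserted, mirroring the design rationale: the cascade
must fit its training distribution (sanity of the whole training path),
and with confounders enabled its mean held-out Dice must not fall below
the single-orientation baseline's across three training seeds (the
directional auto-context benefit; magnitudes at this scale are not
meaningful).

## Known limitations

* The training engine is single-threaded by design (bit-reproducibility
  over throughput) and intended for the desk-scale regime; training
  production-size models on 256^3 data is out of its scope.
* Checkpoint selection on training loss can overfit long schedules.
* The Hausdorff distance is the maximum over full voxel sets — a single
  stray voxel dominates it; no percentile variant is provided.
* Orientation handling covers axis *permutations*, not axis flips: the
  slicing planes are identical either way, so the cascade is unaffected,
  but exported masks inherit the input volume's handedness.
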