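---
title: "Sparse convolutional networks for binary voxel shapes: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse convolutional networks for binary voxel shapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsevox)
```

## The problem

Binarized skull volumes — and many other medical masks — are spatially
sparse: at clinically relevant resolutions, 90% or more of the voxels
are background. A dense 3-D CNN nevertheless allocates features for
every voxel, so its memory grows cubically with resolution. A *sparse*
CNN stores only the occupied coordinates and their features, and all
convolution arithmetic is driven by explicit coordinate management.
`sparsevox` implements such an engine from the coordinate hashing up,
together with two task pipelines: **shape completion** (reconstruct the
full skull from a defective one; the difference is a cranial implant)
and **binary shape super-resolution** (refine an up-scaled coarse mask
into its high-resolution counterpart).

## Data model

A `VoxelGrid` is a dense 0/1 array with voxel spacing and origin — the
I/O-facing form (NRRD, NIfTI-1). A `SparseTensor` is its engine-facing
form: an $N \times 3$ integer coordinate matrix $\mathcal{C}$ plus an
$N \times C$ feature matrix $\mathcal{F}$. Task inputs have one channel
and all features equal to 1. Conventions, fixed once here:

* Coordinates are 0-based voxel indices in $(x, y, z)$ order over
  half-open bounds $[0, X) \times [0, Y) \times [0, Z)$.
* Coordinates always live on the *original* lattice. A stride-2
  downsampling multiplies the **tensor stride** (lattice spacing) by 2
  and keeps coordinates as multiples of it, so encoder and decoder
  lattices reconcile exactly and ground-truth lookups need no
  re-indexing.
* Row order is first-occurrence order of the deduplicated coordinate
  stream, which makes every operation deterministic across runs and
  platforms.

Coordinate lookup uses a hash table keyed by the FNV-1a 64-bit hash of
the coordinates serialized as little-endian 4-byte signed integers, with
exact-coordinate chaining; correctness therefore never depends on hash
quality. `fnv1a64()` exposes the hash; its offset basis and reference
values are pinned in the tests.

## Layers

**Sparse convolution.** For each output coordinate $D'$ and kernel
offset $k$, the input coordinate $D = D' + k \cdot ts$ contributes
$W_k\,\mathcal{F}(D)$ when present; a bias is added at every output row.
A *kernel map* — per-offset lists of (input row, output row) pairs — is
the sparse analogue of the sliding window and is built in C++ in one
pass. Offsets for odd $Ks$ span the symmetric cube
$\{-(Ks-1)/2, \dots, (Ks-1)/2\}^3$; even kernels use
$\{-Ks/2+1, \dots, Ks/2\}^3$ (biased one step positive), the common
sparse-CNN convention, centralized in `kernel_offsets()` so a single
constant controls it. A zero-padded dense reference implementation
(`dense_conv_reference()`) serves as an independent oracle: the two
agree to float tolerance at all computed coordinates for
$Ks \in \{1,2,3,4\}$ and strides $\{1,2\}$.

**Generative transposed convolution.** The output coordinate set is the
kernel-span expansion $\{c + ts_\mathrm{out}\,k\}$ of the input support,
deduplicated — the layer *creates* points, which is what makes sparse
completion possible. Features accumulate over all inputs within the
kernel neighborhood of each output.

**Pruning.** Each decoder stage owns a one-channel, kernel-size-1
scoring convolution; a point is pruned when its score falls below
$\tau = 0$. During training the score is supervised with per-point
binary cross-entropy against the target occupancy coarsened (block-max)
to the stage's tensor stride, and ground-truth points are kept
regardless of score (teacher forcing), so supervision targets are never
starved. At inference only the threshold applies. The scoring-head
construction is this package's resolution of an under-specified detail:
a multichannel intermediate layer has no single "feature value" to
threshold, and a learned scalar score supervised by the ground truth is
the construction consistent with ground-truth-guided pruning that also
yields a usable threshold at inference.

**Normalization.** Each convolution except the final projection and the
scoring heads carries per-channel standardization with an affine
scale/shift (2 parameters per channel). This inclusion is not cosmetic:
the analytic parameter count reproduces the reference totals (0.435M
for `ch1`, 18.14M for `ch2`) only with these 2-per-channel terms, which
was verified against exact enumeration of the built network before the
convention was frozen. Batch statistics are population moments with a
variance floor `eps = 1e-5`; running moments (momentum 0.1) are used at
inference. A **single-row batch has no usable batch statistics** — at
desk-scale grids the deepest encoder stages hold exactly one coordinate,
and standardizing one row would erase it entirely — so training falls
back to the running moments in that degenerate case.

## Architecture

`network_config(ch)` parameterizes the encoder-decoder by a 7-element
channel list. The encoder is one $Ks{=}3$ convolution from 1 channel,
then six blocks of (stride-2 $Ks{=}2$ convolution, $Ks{=}3$
convolution), reaching tensor stride $2^6 = 64$ at the bottleneck. The
decoder mirrors it with six upsample-by-2 generative transposed
convolutions (the first $Ks{=}4$, the rest $Ks{=}2$), each followed by a
$Ks{=}3$ convolution and a scoring/pruning stage, then a final
$1^3$ projection to one channel and a sigmoid. All six decoder stages
upsample by 2 — the only reading under which predictions return to the
input lattice. No skip connections link encoder and decoder (an
experimental `additive_skips` flag exists but is off everywhere in this
package: concatenation skips would change the parameter totals, and the
reference counts match the skip-free reading).

**Initialization.** Fan-in-scaled uniform weights; normalization scale 1
and shift 0; scoring biases +0.5 so an untrained network does not prune
everything; all other biases +0.1. The small positive bias matters on
single-point supports: there ReLU removes whole *channels*, and six
consecutive single-point layers would otherwise kill every feature path
at initialization with high probability (batch standardization, which
normally recenters, cannot apply to one row). The bias is inert wherever
batch statistics do apply.

## Cost models

The analytic parameter count per convolution is
$Ks^3 C_\mathrm{in} C_\mathrm{out} + C_\mathrm{out}$, plus
$2 C_\mathrm{out}$ per normalization; `count_parameters()` must and does
equal exact enumeration over the built tensors. The activation-size
model reports two size recursions side by side: the linear form
$N_i = (N_{i-1} + 2p - Ks)/s$ *as printed in the source material* and
the conventional $\lfloor (N_{i-1} + 2p - Ks)/s \rfloor + 1$; they
differ by one and the discrepancy is surfaced in the report rather than
silently resolved — the substance of the model is the linear scaling,
not the constant. FLOPs per layer are taken as
$N_i \cdot Ks^3 \cdot C_\mathrm{in} C_\mathrm{out}$; the cubed reading
of the kernel term is adopted because a 3-D kernel touches $Ks^3$
positions (the printed text says only "$Ks$").

## Training

The sparse network trains with binary cross-entropy. The final loss is
evaluated over the coordinates surviving the decoder (a sparse output
has no value *at* absent coordinates); ground-truth points missing from
the prediction contribute through the per-stage pruning BCEs — the
mechanism by which the ground truth "teaches the network when to keep or
prune". The total is
$w_\mathrm{final}\,\mathrm{BCE}_\mathrm{final} + w_\mathrm{stage} \sum_j
\mathrm{BCE}_j$. The optimizer is Adam ($\beta = 0.9/0.999$), the
source material naming none; learning rate, epochs and weights are
recorded in every checkpoint, and fixed seeds give bit-identical
checkpoints.

Two engineering guards are worth knowing:

* **Bound clipping.** Inside the task pipelines, coordinates created by
  generative layers are clipped to the voxel domain $[0, \mathrm{dim})$
  — points outside the volume are definitionally empty. Without this an
  *untrained* decoder (whose scoring biases keep everything) expands its
  support combinatorially beyond the grid; with it the worst case is the
  dense grid. The engine layers themselves remain unbounded.
* **Over-pruning diagnostic.** If no point passes the score threshold in
  any training sample for five consecutive epochs, training aborts with
  a diagnostic; transient single-epoch collapses recover through the
  teacher-forced supervision and are tolerated.

For completion, predictions can be united with the defective input
(`union_input`): the task's definition makes the completed skull a
superset of the input. The package default is off (the network is only
*trained toward* that property); the desk-scale completion benchmark
turns it on, and the choice is recorded in the checkpoint.

The dense-baseline ingredients (zero-padded dense convolution and the
two-class squared-denominator Dice loss, minimum $-2$ at a perfect
match) are provided as `dense_conv_reference()` and `dice_loss()`; the
package does not ship a full dense training loop.

## Synthetic data

`make_shell()` produces the region between two concentric ellipsoid
surfaces with a sinusoidal radial perturbation — the minimal family that
is (a) a sparse closed surface (single-digit-percent occupancy, like
binarized cranial bone), (b) has an upper "cranial" region from which
`apply_defect()` cuts spherical or box craniotomy defects (the removed
bone is the implant, and defective + implant = complete exactly), and
(c) carries sub-voxel detail that block-max coarsening destroys and the
super-resolution task must restore. Defaults: semi-axes drawn from
0.60–0.85 of the half-grid, thickness ~2 voxels, perturbation amplitude
2–6% at angular frequency 4–8, rotations within ±0.25 rad, defect
radius 0.25 of the half-grid — values chosen once as a plausible
skull-like regime. What the generator does *not* emulate: anatomical
morphology (facial bones, sutures, foramina), CT noise and artifacts,
and irregular real craniotomy defect shapes. Passing benchmarks on this
family demonstrates that the engine and training machinery work, not
that the trained weights transfer to real skulls.

Block-max downsampling is used for all multi-resolution ground truth
because it never deletes thin structures (a max over each block); the
super-resolution *input* path instead up-scales by trilinear
interpolation with a 0.5 threshold (ties to 1), deliberately producing
the blurry, coarse input the task posits. The coarse grid itself is made
by volume-preserving block-mean coarsening whose boundary class (means
exactly at 5/8 for factor 2) is dithered on a checkerboard — calibrated
once so the up-scaled input carries the same occupied-voxel count as the
target within a few percent, the rearrangement premise of the task
(block-max coarse grids would inflate the up-scaled count by ~60%).

## Desk-scale benchmarks and their limits

The standard benchmark (`run_completion_benchmark()`,
`run_superres_benchmark()`) uses 80 shells (60 train / 20 test) at
$32^3$ (super-resolution: $16^3 \to 32^3$), a
`[4, 4, 8, 8, 16, 16, 32]` channel list, and 8 epochs of Adam at
3e-3 — sizes chosen so the whole suite runs on one CPU in minutes.

One structural fact shapes what these benchmarks can show: at $32^3$
the bottleneck holds a *single* coordinate, so the skip-free decoder
must regenerate the entire shape from one 32-channel code. Desk-scale
training learns the shell family well — the completion benchmark
clears the 0.8 mean-test-DSC bar comfortably, and the
overfit-one-sample oracle reaches DSC > 0.95 — but the generative
reconstruction is not voxel-exact, and thin shells punish every
one-voxel surface error heavily in DSC. Two consequences follow.
Synthetic craniotomy defects at this resolution are small (~3% of the
shell), so the defective input itself scores ≈ 0.98 DSC against the
ground truth; *strictly* beating it would require near-perfect
reconstruction, which a global-bottleneck architecture does not deliver
at this scale — consistent with its published behaviour at the coarsest
(30³) resolution, where completion DSC (0.88) was likewise well below
typical defective-input levels. Trilinear interpolation, the
super-resolution baseline, scores ≈ 0.7 for the same reason (surfaces
approximately right), again above the desk-scale generative ceiling.
The two ordering checks are therefore expected to fail at this scale
and are left honestly failing rather than weakened; they become
attainable only with the data volume, resolution and training budget of
the original study.

Not reproduced here at all (see `reproducibility_notes()`): published
DSC/RE values on the real MRI/CT skull datasets, implant comparisons
against challenge submissions, GPU memory tables and wall-clock timings
— those need the external datasets and GPU-scale training.

## Metric conventions

* DSC of two empty masks is 1; HD95 of an empty mask is `Inf` with a
  warning; both conventions are reported when hit.
* Reconstruction error is the percentage of misclassified voxels; when
  back-computing counts from a printed percentage the product is
  truncated toward zero (fixed by the worked 76772-voxel example).
* Border DSC restricts DSC to a band built by Chebyshev dilation
  (default radius 2) of the ground-truth implant's boundary; the precise
  band used by the external challenge evaluation is not public, so this
  is an approximation and the radius is always reported alongside.
* HD95 pools directed boundary-voxel distances in both directions and
  takes the 95th percentile (type-7 quantile), scaled by voxel spacing.

## Known limitations

* Orientation handling for NIfTI is limited to spacing; full affine
  support is out of scope.
* Batching is available in the data model (leading batch index) but the
  pipelines train with batch size 1.
* The engine is single-threaded by contract (sequential determinism);
  there are no GPU kernels.
* Mesh voxelization is not implemented; any future mesh path must pick a
  fill convention explicitly.
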