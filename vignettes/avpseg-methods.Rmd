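---
title: "Methods: cascaded aVP segmentation, phantom design, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cascaded aVP segmentation, phantom design, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model
and its assumptions, the tunable parameters with their defaults and
why, what the synthetic phantom emulates (and deliberately does not),
the numerical conventions, and the design decisions that were genuinely
open. It states no empirical result that the test suite does not itself
recompute.

## 1. The problem and the data model

The anterior visual pathway (aVP) — both optic nerves, the chiasm, and
both optic tracts — is a thin, curved, bilateral structure a few
millimetres across. On heavily T2-weighted steady-state MRI (CISS-like
contrast) the nerve appears dark inside a bright cerebrospinal-fluid
sheath; that nerve–fluid interface is what makes automated delineation
feasible at sub-millimetre isotropic resolution, and it is the only
image property the method actually relies on.

`avpseg` represents an image as an `avp_volume` (3D array + voxel
spacing in mm + a 4×4 voxel-to-world affine) and a segmentation as an
`avp_labelmap` bound to a fixed ten-class scheme: background plus nine
structures, each nerve subdivided into intraorbital (iOrb),
intracanalicular (iCan) and intracranial (iCran) segments, the chiasm
(ONC), and the two tracts (OTR, OTL). Integer codes 0–9 are frozen so
label maps travel as unsigned 8-bit NIfTI; a JSON sidecar documents the
scheme. Orientation is canonical RAS-like: with a positive first
diagonal of the affine, increasing first-axis index is the anatomical
right; laterality decisions read this sign rather than assuming it.

**Union ground truth.** The reference standard merges two readers'
delineations by set union: any voxel marked by either reader is
foreground. The union is exact by construction. The source material
specifies only the union of foregrounds; what to do when the readers
assign *different* labels to the same voxel is undefined there, so the
package resolves conflicts by reader-1 priority and counts every
conflict in a 9×9 table. This choice is arbitrary but deterministic and
fully reported.

## 2. The synthetic phantom: a stated world

No clinical data ship with the package, so every downstream stage is
exercised on parametric phantoms (`phantom_spec()`,
`generate_phantom()`).

Geometry: each optic nerve is a tube swept along a cubic Bézier curve
from an anterolateral orbital point to the chiasm; the chiasm is an
ellipsoid; the tracts are tubes diverging posteriorly. Nerve arc length
is split 0.5/0.2/0.3 into iOrb/iCan/iCran. Voxels are assigned to the
structure with the largest membership margin (tube radius minus
centerline distance, or the ellipsoid equivalent), which guarantees the
26-connected iOrb→iCan→iCran→ONC→tract chain on each side.

Defaults state the emulated world: 0.6 mm isotropic voxels (the
acquisition the method targets), a 64×64×32 desk grid, a 1.5 mm nerve
tube radius with 0.2 mm between-subject SD (a plausible adult caliber —
the true population distribution lives in the anatomical literature and
is *not* modelled), a 4.5 mm chiasm half-width, a 1 mm fluid sheath.
Contrast levels (arbitrary units): nerve 0.35, fluid 0.85, orbital fat
0.9, bone 0.05, background 0.4, Gaussian noise SD 0.04. Only the
nerve–fluid contrast matters to the method; the rest is scenery.
Two failure modes reported for real data are injected deliberately:

- **canal shading** — a multiplicative radial signal drop (default 35%
  over a 3 mm extent) centred on the intracanalicular segment, mimicking
  susceptibility-induced degradation inside the bony optic canal;
- **tract end-slice truncation** — the simulated readers randomly
  truncate the posterior tract end (SD 1.2 mm), the locus of most
  inter-reader disagreement.

`perturb_reader()` emulates a human reader: stochastic one-voxel edits
along structure boundaries (probability 0.35 per boundary voxel per
pass), Gaussian jitter of each segment-transition plane (SD 0.8 mm),
and the tract truncation above. These defaults were tuned once so that
reader-vs-truth whole-pathway Dice lands in [0.75, 0.98] and then
frozen as a regression band; with them, simulated reader pairs agree at
Dice ≈ 0.85–0.9, close to what expert readers achieve on real aVP data.
The perturbation moves boundaries but never topology; topological
defects are the post-processing tests' job, injected by dedicated
fixtures.

**What a green phantom test does not establish:** the phantom has no
bias fields, no motion, no pathology, no partial-volume modelling
beyond voxelization, and MR signal is painted, not simulated from spin
physics. Passing on phantoms demonstrates the machinery is correct and
the cascade can learn this geometry — not clinical performance.

## 3. Networks and losses

The principal network is a 3D encoder–decoder: strided-convolution
downsampling (depth 3 by default), a symmetric nearest-neighbour
upsampling decoder, residual multi-scale (Res2-style, scale 4)
convolutions confined to the bottleneck, additive attention gates on
the skip connections, ReLU activations throughout, and an auxiliary
class head at half resolution (deep supervision, weight λ = 0.4). The
refinement network is a lighter attention U-Net (width 6 vs 8, plain
bottleneck, no auxiliary head — strictly fewer parameters at matched
depth) whose input is the image concatenated with the principal
network's softmax probabilities.

All of this is implemented directly in R over compiled 3D convolution
kernels with hand-derived backpropagation, verified against central
finite differences to ~1e-5 relative error in the tests. Three
implementation choices deserve explanation, because the source material
specifies none of the training details:

- **Instance normalization** (per-channel, learnable scale/shift) after
  every 3×3 convolution. Without it, pure soft-Dice training of a
  randomly initialized network collapses to all-background within a few
  steps at desk scale — a known failure mode with extreme class
  imbalance (foreground is ≈ 2% of voxels here).
- **Background-inclusive training Dice.** The *reported* Dice loss
  averages the nine foreground classes, as defined. The *training*
  objective additionally includes the background class in the average
  (`include_background = TRUE`): the foreground-only loss exerts no
  upward pressure on the background probability, and at desk scale one
  foreground class reliably swallowed the background. The exported loss
  defaults are unchanged.
- **Refinement input-logit skip.** The refinement head's logits add
  `log(p + 1e-4)` of the incoming class probabilities, so the untrained
  refiner starts at (approximately) the identity over the principal's
  segmentation and learns *corrections* under the boundary-weighted
  loss. Without this, a refiner trained for a handful of epochs
  degraded the cascade badly. The training target remains the full
  multiclass ground truth — this is an architectural skip, not a
  residual-target reformulation.

The boundary weight map is `w(v) = 1 + (w_max − 1)·exp(−d(v)/τ)` with
`w_max = 5`, `τ = 2` voxels, and `d` the Euclidean distance to the
nearest voxel whose 6-neighbourhood contains a different label; the
weighted soft Dice reduces exactly to the plain one at `w ≡ 1`.
Soft-Dice smoothing is ε = 1e-5; argmax ties resolve to the lowest
class id. Optimization is Adam (lr 1e-2, β = 0.9/0.999), one
full-volume subject per step — at 48×48×24 there is no memory pressure
and full volumes avoid patch-border artifacts.

## 4. Pipeline: splits, gate, vote, post-processing

Monte Carlo cross-validation repeats random 80/20 train/validation
partitions until every subject has been validated at least once
(`make_mc_splits()`, hard cap `max_runs = 20` by default — failure to
cover is an *error*, never silent). Note that for large cohorts twenty
runs are not statistically sufficient for coverage (with n = 80 the
per-subject miss probability is 0.8²⁰ ≈ 0.012, so full coverage within
20 runs is a coin flip); callers wanting guaranteed coverage on big
cohorts should raise `max_runs`. Budgeted experiments that just need k
folds use `make_fixed_splits()`.

The refinement gate retains exactly the subjects whose mean Dice
(unweighted mean over the foreground labels present in that subject's
ground truth — the averaging set was an open choice) is ≥ 0.7,
inclusive at the boundary. Majority voting assigns a voxel to class c
iff strictly more than θ = 0.5 of the models predict c; strictness
makes the winner unique and sends exact 50/50 splits to background.
Votes are hard labels, post-argmax. The ensemble pools the models of
all folds — the alternative (a fixed subset) was left ambiguous in the
source; pooling is the simpler, better-performing reading.

Post-processing applies four operators per sweep, iterated to a
bounded fixpoint (≤ 4 sweeps; a sweep that changes nothing
terminates):

1. **gap interpolation** — per label, if the label has more than one
   connected component, a morphological closing with a line element
   (length 5 voxels) along the label's principal axis, filling
   background only, never overwriting other labels;
2. **cluster removal** — keep the largest 26-connected component per
   label (size ties broken toward the image centre);
3. **side enforcement** — the midline sagittal plane passes through the
   chiasm centroid (or an explicit override; prediction falls back to
   the image centre when the chiasm is missing entirely); a sided
   component whose centroid lies strictly on the wrong side is
   relabelled contralaterally, exact-midline centroids untouched;
4. **continuity correction** — non-adjacent consecutive chain segments
   are joined by a 1-voxel straight bridge between nearest surface
   voxels through background only (≤ 3 mm; longer gaps are reported,
   not bridged), labelled by the nearer segment up to the midpoint.

Two deliberate deviations from the initially-specified design: gap
interpolation runs *before* cluster removal (removal-first deletes half
of any thin structure transected by a small gap — exactly the defect
the operator exists to repair), and closing is conditional on the label
being disconnected (unconditional directional closing is extensive on
curved tubes, so clean anatomy would not be a fixpoint). The fixpoint
iteration makes idempotence — `postprocess(postprocess(x)) ==
postprocess(x)` — hold by construction.

## 5. Metrics and reporting

Overlap metrics follow the printed formulas exactly, with documented
empty-mask conventions: both-empty → DSC/Jaccard/VS = 1, one-empty →
0; empty masks are an *error* for distance metrics, and
`evaluate_subject()` records the reason instead of a number. Surface
voxels are mask voxels with a 6-neighbour outside the mask (the image
border counts as outside). Distances are computed by an exact Euclidean
distance transform (Felzenszwalb/Huttenlocher lower envelopes per axis,
anisotropic spacing in mm) sampled at the other surface's voxels —
algebraically identical to the all-pairs computation, and verified
against it to 1e-9 on random masks. HD95 is the maximum of the two
directed 95th percentiles (`stats::quantile` default type); directed
pooling was unspecified in the source and this is the common
convention. Whether distances should use surface voxels or full masks
was also unspecified; with thin tubes the difference is small, and the
surface convention is pinned by the oracle tests.

Summaries assume a t-distribution with N − 1 degrees of freedom:
`mean ± t₀.₉₇₅,ₙ₋₁ · SD/√n`, reported as (mean, CI low, CI high, SD, n)
per (structure, metric) — the standard report layout. With n < 2 the CI
is flagged undefined rather than fabricated.

## 6. Desk scale, budgets, and limitations

The test and acceptance configuration is deliberately small: base width
8, depth 3, 8 phantoms at 48×48×24, 3 Monte Carlo folds, 16 + 6
epochs — about ten CPU-minutes end to end. (The nominal desk grid of
16 phantoms at 64×64×32 trains the same way but takes roughly 3× as
long; the smaller grid is the sanctioned fallback for a one-CPU
budget.) A full-scale 256×256×64 configuration is expressible with the
same code (`network_config()`, `standardize()`) but is not exercised by
any test.

Known limitations: the NIfTI reader handles the common single-file
datatypes and the sform affine (quaternion-only files fall back to a
diagonal affine with spacing from `pixdim`); spacing and affine survive
the float32 header round trip via 7-significant-digit normalization;
training determinism holds for a fixed machine and seed (pure R/C++
arithmetic, no threaded reductions), but bitwise identity across
different BLAS builds is only relevant to the dense heads, not claimed
globally; and all learning claims are phantom-scale — nothing here has
seen a patient.
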