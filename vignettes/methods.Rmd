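---
title: "Methods: multi-atlas segmentation for the neonatal rabbit brain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-atlas segmentation for the neonatal rabbit brain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models and numerical choices behind
`rabatlas`: the stereotaxic frame, the taxonomy conventions, the four
similarity metrics, the fusion algorithms, the builtin registration, the
atlas builder, and the synthetic phantom the test suite runs on.

## Coordinate conventions

All world coordinates are NIfTI RAS+ millimetres (+x right, +y
anterior, +z superior); voxel indices are 0-based in the affine and
1-based at the R array surface, with the conversion hidden in
`voxel_to_world()` / `world_to_voxel()`. Every distance the package
reports is in world mm computed through the grid affine, never in voxel
units, so anisotropic grids are handled uniformly.

## Stereotaxic reorientation

Skull landmarks are unreliable in the developing head, and the rodent
convention of a horizontal bicommissural plane gives an awkward coronal
plane in the rabbit. `stereotaxic_transform()` therefore builds the
rigid map (rotation determinant +1, plus translation) that sends the
mid-sagittal plane to `x = 0`, the anterior commissure center to the
origin, and the AC→PC direction into the `x = 0` plane at 45° below
horizontal, PC posterior-inferior. The construction is closed-form: two
orthonormal frames (plane normal, in-plane AC→PC direction, their cross
product; and their canonical targets) define the rotation. Placing the
origin at the AC is a package convention — the angle rule does not fix
an origin — and is configurable through the landmark input. Automatic
AC/PC detection is out of scope; landmarks are user input (in practice
they were located manually).

Degenerate input (AC ≈ PC within `tol = 1e-6` mm, or AC→PC orthogonal
to the mid-sagittal plane) is an error rather than a guess.

## Taxonomy and macro-regions

The packaged taxonomy has 89 regions in a dotted hierarchy. Symmetric
structures follow the left/right odd/even id convention, but pairing is
stored as explicit mutual `pair_id` metadata and *never* derived from
parity: the table contains an odd median id (77, basal forebrain), an
even median id (78, septum), and a lone even id (218, corpus callosum),
so parity arithmetic would silently corrupt a hemisphere flip.
`side_swap_map()` is validated to be an involution. Unknown labels in a
volume are an error by default (a warning on request), because silent
label drift is the main maintenance hazard of a versioned atlas.

The default macro-region map groups the 89 regions into 16 disjoint
macro-regions whose union is exactly the taxonomy; both counts are
asserted in the acceptance suite. ITK-SNAP label files are exported
with a seeded random palette (the source material publishes no colors,
so they are generated, not reproduced; a fixed seed makes re-exports
byte-identical).

## Similarity metrics

Four complementary measures compare two delineations `A1`, `A2`:

* **Dice** `2|A1∩A2|/(|A1|+|A2|)`. Two empty regions give a missing
  value (`NA`), never `0/0`.
* **Covariance distance** compares the 3×3 covariance matrices of the
  regions' world-coordinate point clouds, scaled by the maximal
  dissimilarity `α = 10`. The default normalizes the inner product by
  the *product* of Frobenius norms,
  `α(1 − Tr(c1c2)/(‖c1‖·‖c2‖))`, under which identical (or
  proportional) covariances score exactly 0 and `Tr(c1c2) = 0` scores
  exactly `α` — by Cauchy–Schwarz the value always lies in `[0, α]`. A
  variant normalizing by the *sum* `‖c1‖+‖c2‖` is available as
  `covdist_variant = "literal_sum"`; it is not the default because it
  does not vanish for identical regions and is not bounded by `α` in
  general, which contradicts the "maximal possible dissimilarity" role
  of `α`. Covariances use the unbiased (n−1) estimator; rank-deficient
  covariances warn but are allowed; an all-zero covariance against a
  non-zero one scores `α`.
* **Symmetric Hausdorff distance** and **NSCD** are computed between
  *internal contours*: the region voxels with at least one 6-face
  neighbour outside the region, with out-of-grid counting as outside.
  NSCD sums the minimal contour-to-contour distances both ways and
  divides by the total contour size, making it an outlier-robust
  counterpart of the Hausdorff maximum; `NSCD ≤ HD` always. Minimal
  distances are found with a chunked expanded-form search and the
  winning pair's distance is then recomputed directly, so results match
  an O(n²) exhaustive oracle to ~1e-8 (asserted on 100 random masks in
  the tests).

Per-label reports emit `NA` rows for labels empty in either input —
mirroring the explicit exclusion of non-overlapping regions in
test-retest reporting — rather than scoring them 0.

## Label fusion

Majority voting takes the per-voxel modal label. Ties go to the
smallest label id by default (a seeded random policy is available);
determinism here keeps the whole atlas-building loop reproducible, and
smallest-id (rather than stack order) keeps fusion invariant to atlas
permutation.

STAPLE is implemented as the multi-label EM: hidden true label `T(x)`,
per-atlas confusion matrices `θ_i(t, s) = P(observed s | true t)` (rows
= true, normalized), E-step posteriors computed in log space from the
current `θ` and a per-voxel prior, M-step re-estimating `θ` from the
posteriors with a `1e-6` row regularization (which also absorbs
degenerate, constant-output raters). The prior is the per-voxel vote
frequency; the spatial-homogeneity constraint of the original
formulation is available as a mean-field term — the prior is sharpened
by `exp(β · mean neighbour posterior)` with weight `β` (default 0,
since no strength is published for the original study). The model
log-likelihood is asserted non-decreasing in every test run;
non-convergence within `max_iter` returns the last iterate with a
warning. Initialization: `θ` diagonal 0.9, off-diagonal uniform.

STEPS is implemented as LNCC top-`k` gating composed with the
restricted STAPLE EM: each atlas's warped channels are compared with
the target by Gaussian-windowed local correlation (per-modality maps
averaged with configurable weights; the multi-modal default is the
unweighted mean of T1 and FA), atlases below the per-voxel `k`-th rank
contribute neither to the E-step nor the M-step at that voxel, and rank
ties at the cutoff retain all tied atlases (order invariance). With
`k = N` and `β = 0` STEPS reproduces `staple()` bit-exactly, which the
tests assert. This is a deliberate, documented simplification of the
original STEPS formulation, whose full MRF machinery is out of scope.

LNCC windows are Gaussian with `sigma` in mm; local means use
boundary-renormalized convolution; voxels whose local variance is below
`1e-8` of the image maximum variance are flagged and scored 0.

The default fusion grid mirrors the 8 mono-modal + 8 multi-modal
protocol: per modality set {T1} and {T1, FA}: majority voting, STAPLE,
and STEPS at window sigmas {0.5, 1, 2} mm × kept-atlas counts
{⌈N/2⌉, N−1}. The exact original parametrizations are unpublished, so
this grid is a documented stand-in, not a reproduction. For automatic
segmentation the default fusion is multi-modal majority voting, the
configuration that scored best in the original validation.

## Registration

`register()` is a contract: any backend producing a target-to-source
point map can stand behind it (`backend = "external"` runs a command
template and reads back a dense displacement field). The builtin
backend is intentionally desk-scale:

1. **Moments initialization** — center-of-mass translation, then a
   Nelder-Mead rigid (optionally affine) search on a ≤24³ pyramid
   level. Two numerical safeguards matter here. First, the moving image
   is pre-blurred with the same kernel the fixed pyramid level
   received, so the objective compares equally band-limited images
   (otherwise the comparison is biased toward poses that blur the
   moving image through interpolation). Second, the searched pose is
   accepted only if it improves on the initialization by more than
   `2·mad(highpass(moving))²` — the interpolation of a noisy image can
   lower an SSD objective by up to its noise variance for *any*
   sub-voxel shift, and this floor keeps the search from drifting on
   noise when the images are already aligned.
2. **Demons-style SVF refinement** — multiresolution (default 3
   levels, 40/30/15 iterations), symmetrized-gradient Thirion forces,
   per-iteration fluid smoothing (`sigma_fluid`, default 1.5 voxels) of
   the update and diffusion smoothing (`sigma_diffusion`, default 1
   voxel) of the velocity, update magnitude capped at 1 voxel, and a
   noise gate: mismatches smaller than `noise_gate = 3` times the
   per-level noise floor (median absolute deviation of the fixed
   image's high-pass residual) generate no force. Without the gate the
   field drifts through homogeneous regions chasing noise texture and
   can degrade label alignment even while decreasing intensity MSE.

Velocity fields are exponentiated by scaling and squaring with the step
count chosen so the scaled displacement is below half a voxel; the
inverse is the exponential of the negated velocity, and the composition
`exp(v)∘exp(−v)` stays below 0.1 voxel mean residual on the smooth
fields used in tests. Labels are always resampled nearest-neighbour —
probabilistic per-label resampling was rejected for determinism — so
propagation can never invent a label id.

## Pipeline, refinement, validation

`segment_new_subject()` registers each atlas's T1 to the target inside
the ROI masks (an artifact mask, built by `percentile_artifact_mask()`,
further restricts the registration region), propagates segmentations
(nearest) and channels (linear), and fuses. If the target lacks an ROI
mask, the first atlas's mask is propagated through a rigid
registration. Failures of individual atlases exclude them with a
warning; fusion proceeds while at least one atlas survives. Every run
logs atlas ids, fusion settings, seed, and per-atlas timings.

The artifact mask keeps ROI voxels at or below a chosen intensity
percentile. The percentile is the *inclusive nearest-rank* value — the
sorted ROI intensity at rank `floor(p·n/100)+1` (capped at `n`) — so
e.g. 100 uniformly ranked voxels at the 90th percentile keep 91; this
convention is asserted in the tests.

`iterative_refinement_round()` re-segments one subject from all others
and stores the result as a versioned automatic layer next to any manual
layer; manual edits are external events, so repeated rounds without new
manual input are a fixed point. `loo_cross_validation()` runs the
leave-one-out harness and reports median/IQR/min/max per macro-region
and metric, the same statistics a box-plot presentation uses.

Mask symmetrization alternates Gaussian smoothing (sigma in mm),
averaging with the mirror image about the mid-sagittal plane, and
thresholding at 0.5, for a configured number of iterations. The 0.5
threshold on the smooth/mirror average means thin one-sided structures
erode unless they are large enough for the smoothed interior to reach
1; this matches its intended use on a coarse brain/skull ROI, not on
fine parcels.

## Group-wise template and probabilistic atlas

`groupwise_template()` iterates register-to-template / average /
de-bias. De-biasing resamples the average through the *mean* forward
displacement of the subject maps and re-expresses each subject
transform in the de-biased coordinates, so the mean final deformation
is zero to first order and the template sits at the population
barycenter instead of drifting toward any subject (order-permutation
invariance is tested). Iterations default to 4; the template stage uses
the T1 channel only, with multimodal similarity left as a configuration
hook. Divergence (growing template change) stops the loop with a
warning.

Probabilistic label maps average *hard* indicators: the probability of
label L at a voxel is the fraction of subjects whose nearest-neighbour
propagated segmentation carries L there. Indicator averaging was chosen
over soft resampling because it makes the partition-of-unity exact
(label probabilities plus background sum to 1 at every voxel, asserted
to 1e-6), at the cost of blockier maps at small sample size.

## The synthetic phantom

The phantom provides the structure the pipeline assumes of a real
cohort, at desk scale: a midline-symmetric nested-ellipsoid
parcellation (default 6 left/right wedge pairs plus 3 midline shells on
a 36×44×30 grid at 0.4 mm isotropic), AC/PC landmarks already in
canonical pose, a generated taxonomy following the odd/even pairing
convention, per-subject random smooth diffeomorphisms (white-noise
velocity smoothed with sigma 3 voxels, scaled to a 1 mm peak) composed
with rigid jitter (2°, 0.3 mm), and three intensity channels with
per-label means, additive Gaussian noise, and a smooth multiplicative
bias field (log-amplitude 0.08). The FA-like channel highlights the
midline "fibertract" shells so that the multi-modal pathway carries
information the T1 channel alone does not. The deformation defaults put
single-atlas propagation Dice in the 0.7–0.95 range — the regime where
fusion demonstrably helps — and are asserted to conserve every label.

Simulated raters keep a foreground voxel with probability
`sensitivity` and a background voxel with probability `specificity`;
errors take the label found at a small random offset (or the next label
id if that equals the truth), so mistakes are spatially plausible
rather than uniform. Everything is deterministic given the seed.

What the phantom does *not* emulate: real rabbit neuroanatomy, MR
physics (ghosting, susceptibility, EPI distortion), partial-volume
mixing at boundaries, or inter-subject intensity covariance. Passing
tests therefore demonstrate algorithmic correctness and the expected
qualitative behaviour (fusion beats single atlases, STAPLE recovers
rater performance, registration recovers known warps), not clinical
segmentation accuracy on scanner data.

## Problem sizes and tolerances in the test suite

The suites run on grids between 20³ and 48×52×42 voxels with 2–5
subjects or raters: large enough for the statistical checks (the STAPLE
recovery phantom exceeds 10⁵ voxels; rater recovery is asserted within
±0.02), small enough that the whole suite, including the four-fold
leave-one-out fusion-benefit experiment, completes in a few minutes.
Oracle-equivalence tolerances are 1e-8 against brute-force metric
oracles and 1e-8 against the independently coded STAPLE EM; the
stereotaxic angle is recovered to 1e-6 degrees over 100 random poses;
diffeomorphism contracts are held to 1e-6 (closed forms) and 0.1 voxel
(inverse-consistency residual).

## Known limitations

* The builtin registration is adequate for phantom-scale grids; full
  resolution micro-MRI volumes need the external backend.
* Grids are assumed axis-aligned for SVF velocity storage (the affine
  may scale and translate; oblique rotations are untested).
* STEPS omits the original MRF coupling; STAPLE's spatial term is a
  mean-field approximation with an unpublished weight, default off.
* The mid-sagittal plane comes from landmarks; no automatic symmetry
  optimization is provided.
* Bias-field correction and diffusion-tensor fitting are upstream
  preprocessing; the package consumes their outputs (FA/MD channels)
  and does not reimplement them.
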