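---
title: "Quantifying meniscal motion from knee MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying meniscal motion from knee MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

The two menisci are crescent-shaped fibrocartilage pads that glide on the
tibial plateau as the knee moves.  Quantifying how far and in which
direction each meniscus travels between two knee positions — say, maximal
internal and external tibial rotation under a defined torque — requires
bringing two 3D MR volumes of the same knee into a common frame and then
measuring residual soft-tissue displacement.  `meniscusmotion` implements
this as a two-stage registration pipeline operating on a volume plus
binary segmentation masks (tibia, medial meniscus MM, lateral meniscus LM)
per position:

1. **Tibia-anchored rigid alignment.** A 6-DOF rigid transform is
   estimated by minimising the sum of squared intensity differences
   restricted to the template tibia mask.  Because the similarity only
   sees the bone, whole-knee repositioning is removed and all subsequent
   displacements are *relative to the tibia*, which is the clinically
   meaningful frame.
2. **Curvature-regularised deformable registration of the menisci.** A
   dense displacement field `u` (mm, on the template grid) minimises

   `J[u] = SSD(T, M, u) + alpha * S[u] + beta * P[u]`

   where `T` and `M` are Gaussian-smoothed indicator images of the
   template and (rigidly aligned) moving meniscus masks,
   `SSD = 1/2 * sum (T(x) - M(x + u(x)))^2 * dV`, the curvature
   regulariser `S[u] = 1/2 * sum_l integral (Laplacian u_l)^2` penalises
   bending of each displacement component (affine fields, in particular
   rigid residuals, are free), and `P[u]` is a distance-transform shape
   penalty described below.  The convention throughout is that `u`
   carries a template voxel to its position in the moving image, i.e. it
   *is* the motion of that piece of tissue.

The field is then cropped with the template meniscus masks, each meniscus
is partitioned into three equal-arc-length segments (anterior,
intermediate, posterior horn), and the per-segment mean displacement
vector is projected onto anatomical axes derived from a principal
component analysis of the combined meniscus voxel cloud.  Positive ML
means lateral, positive AP means posterior.  Cohort tables report mean
and sample SD per condition/meniscus/segment/measure, and paired Wilcoxon
signed-rank tests compare conditions and menisci without multiplicity
adjustment (the analysis is exploratory by design).

# The distance penalty and its orientation

SSD on mask indicators has a capture range of roughly the smoothing
kernel: if the menisci do not overlap between positions at all, its
gradient carries no information about where the counterpart lies.  The
shape penalty fixes this:

`P[u] = 1/2 * sum_{x in template meniscus} D_mov(x + u(x))^2 * dV`

where `D_mov` is the Euclidean distance map of the moving meniscus mask
(computed once per pair by an exact separable distance transform,
spacing-aware, in mm).  Three properties motivated this exact form:

* it vanishes exactly at the true motion (every template meniscus voxel
  warps onto the moving meniscus);
* its support is the *fixed* set of template-mask voxels, so the solver
  cannot cheat by thinning the sampled indicator mass — a degenerate
  minimum we observed with the alternative "pulled-back indicator times
  template distance map" formulation;
* `|grad D| = 1` almost everywhere, so the pull towards the counterpart
  is defined at any separation; this is what lets two masks six
  millimetres apart, with zero initial overlap, register to high Dice.

Sampling of `D_mov` outside the grid returns the map's maximum, so
leaving the field of view is never rewarded.

# Optimisation

The objective is minimised by a matrix-free Gauss-Newton method.  Each
outer iteration linearises the residuals at the current field and solves
the normal equations by preconditioned conjugate gradients using only
operator-vector products: the SSD and distance blocks are per-voxel 3x3
outer products of sampled image gradients, and the curvature block is two
applications of the discrete Laplacian (the operator and its adjoint),
fused into a single compiled kernel.  A Jacobi preconditioner
(the Hessian diagonal) tames the stiffness of the fourth-order curvature
operator.  Steps pass an Armijo backtracking line search (factor 0.5,
slope parameter 1e-4), so accepted iterates never increase the
objective; if the line search fails the level terminates.  The whole
solve is embedded in a factor-2 multilevel pyramid (Gaussian anti-alias,
coarsest grid at least 8 voxels per axis) to avoid local minima; the
coarse solution is trilinearly prolonged and then smoothed with a
one-voxel Gaussian, because raw piecewise-linear upsampling carries slope
kinks that the fine-level curvature term would misread as bending energy.
There are no stochastic steps anywhere in the solver: results are
bit-reproducible for identical inputs.

In the subject pipeline the deformable stage is additionally initialised
with a translation pre-alignment built from the per-meniscus mask
centroid shifts, applied through Gaussian windows of the template-mask
distance maps (`init_field_from_centroids()`).  Meniscal travel of
5-8 mm spans several voxels; without the head start the Gauss-Newton
iterations spend most of their budget diffusing a large translation
through the regulariser.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `alpha` | 1.0 | — | curvature weight; larger = smoother field |
| `beta` | 0.1 | mm^-2 | distance-penalty weight; provides capture range |
| `smoothing_sigma` | 1 | voxels/level | indicator smoothing driving SSD |
| `n_levels` | 3 | — | multilevel depth (factor 2) |
| `max_iter_per_level` | 50 | — | outer Gauss-Newton cap |
| `tol_rel` | 1e-4 | — | relative objective-decrease stop |
| `cg_max_iter` / `cg_tol` | 100 / 1e-2 | — | inner CG budget |

`alpha` and `beta` are not identifiable from first principles; the
defaults were validated by parameter-recovery experiments (translation
and Gaussian-bump fields with known truth, see the test suite).  The
inner CG budget matters more than is obvious: with only a few tens of
iterations the Newton system of the stiff curvature operator is solved so
poorly that recovered motion is visibly shrunk toward zero; 100
preconditioned iterations removed that bias in our recovery tests.

## Discretisation choices

Voxel indices are 0-based and refer to voxel centres; the voxel-to-world
map is the NIfTI affine (RAS, mm).  All sums carry the voxel volume so
term values are resolution-consistent integrals.  The Laplacian uses
second-order central differences with anisotropic spacing; at the grid
boundary the field is extended linearly ("free" boundary, zero second
derivative), which makes the discrete operator annihilate affine fields
exactly — a property the regulariser needs so that residual rigid motion
is never penalised.  The boundary rows of the operator are therefore
empty, and the curvature gradient uses the exact adjoint of this
asymmetric operator.  Out-of-domain samples of images and masks are 0
(background); out-of-domain samples of distance maps are the map maximum.

# Anatomical axes and segment partition

The AP/ML axes come from the eigenvectors of the covariance of the
combined MM+LM voxel coordinates: the plateau plane is spanned by the top
two principal directions.  Of these, the one carrying the larger
projection of the LM-minus-MM centroid difference becomes ML (signed so
positive points lateral, i.e. from MM towards LM); the in-plane
complement becomes AP, signed posterior using the world frame's anterior
axis.  The laterality flag cross-checks that "lateral" agrees with the
patient side and warns on mismatch (typically swapped mask files).  Both
menisci enter one PCA because a single joint frame is needed to compare
MM and LM motion.

For the three-segment partition each meniscus is projected into the
principal plane and parameterised by polar angle about the centre of the
circle fitted to its voxel cloud (algebraic least-squares fit).  We use
the fitted arc centre rather than the area centroid deliberately: for a
wide-span crescent the centroid sits well off the arc centre, polar
wedges about it slice the crescent ends obliquely, and the end segments
absorb far more than a third of the arch.  Arc length is accumulated
along the angularly binned centreline (`ds = sqrt(dr^2 + (r dtheta)^2)`,
2-degree bins, 7-bin running-mean smoothing of the binned radius — the
raw per-bin voxel means carry lattice noise of the order of a voxel that
would otherwise dominate `|dr|`), and cut at 1/3 and 2/3 of the total.
The end whose centreline endpoint is more anterior becomes the anterior
horn.  Masks forming a closed annulus (angular gap below 10 degrees) or
disconnected masks are rejected: the arch has no endpoints.

Per segment, the report is the norm of the mean displacement vector
(`avg_mm`) and the signed ML/AP projections of that mean.  The norm of
the mean (not the mean of norms) matches reporting one direction per
segment; consequently the cohort-level `Avg` need not equal
`sqrt(ML^2 + AP^2)` of the cohort-level components.

# Wilcoxon signed-rank machinery

Paired comparisons use the classic Wilcoxon treatment: zero differences
discarded, mid-ranks on ties, `W` = rank sum of positive differences.
The exact two-sided p-value comes from the full null distribution of `W`,
computed by convolution over the doubled mid-ranks (doubling makes them
integers, so the distribution stays exact under ties).  In `auto` mode
exact enumeration is used up to 25 effective pairs on tie-free data,
otherwise a normal approximation with tie-corrected variance and
continuity correction — the behaviour of mainstream statistics packages
at a 31-subject scale.  The test suite checks the exact path against
brute-force enumeration of all sign assignments and against
`stats::wilcox.test` on tie-free data.

# The synthetic knee phantom

Because the in-vivo cohort data behind the published tables are not
deposited, validation rests on digital phantoms with analytically known
motion.  A phantom is a tibial segment — an elliptical plateau with an
anterior tuberosity lobe and a smooth trabecular-like internal intensity
texture — topped by two annulus-sector crescents (MM modelled with larger
radius and wider angular span than LM, both opening towards the joint
midline).  The asymmetric bone shape and texture are not decoration: a
rotationally symmetric tibia would leave the in-plane rotation component
of the rigid stage unidentifiable.  Default resolution follows a
high-resolution knee protocol (0.6 x 0.6 x 0.5 mm); Gaussian intensity
noise defaults to 2% of the tissue contrast, since stage 2 operates on
masks and noise mainly exercises stage 1.

Ground-truth motion composes, in order: a smooth local field (per-meniscus
in-plane translations applied through compact C1 windows that are exactly
1 on the owning meniscus, exactly 0 on the tibia and beyond a finite
support radius, plus an optional Gaussian displacement bump), an in-plane
tibial rotation about the plateau centre, and a global rigid
repositioning.  Because the local field vanishes on the tibia, the motion
*relative to the tibia frame* — what the pipeline measures after rigid
alignment — is exactly the local field, and on the meniscus voxels
exactly the drawn translation.  Moving images are rendered through the
analytic inverse (exact for the rigid part, fixed-point iteration for the
local part; translations are restricted to the plateau plane so the map
is a shear in z and the iteration provably contracts).  Window ramps are
smoothsteps whose slope bounds the displacement gradient at
`1.5 |t| / window_width`; motions violating invertibility are rejected,
and the cohort simulator redraws such (rare, > 3 sigma) translations.

The cohort simulator draws per-subject, per-condition meniscal
translations in anatomical components, with generating means and SDs
defaulting to the published whole-meniscus pattern for internal/external
rotation under 5 Nm torque — LM posterior-medial and MM slightly
anterior-lateral under internal rotation, roles reversed under external
rotation, so MM and LM move in opposite AP directions in both conditions
— plus a 10-degree tibial rotation and whole-knee repositioning noise
(1 degree / 1.5 mm SD).  Laterality alternates right/left so the
ML-sign logic is exercised on both knees.

**What the phantom does not emulate:** femur and cartilage, MR physics
(coils, sequences, artifacts, bias fields), segmentation errors (masks
are exact by construction), through-plane meniscal motion, and genuinely
non-rigid tissue deformation beyond the smooth bump model.  Passing the
recovery tests therefore demonstrates that the *pipeline* is correct and
accurate under its stated motion model, not that segmentation-derived
in-vivo measurements carry the same sub-half-millimetre accuracy.

# Problem sizes

Validation runs use a 96 x 96 x 64 voxel phantom at 0.6 x 0.6 x 0.5 mm
for rigid recovery, 1 mm isotropic grids of about 56 x 56 x 24 voxels for
deformable recovery and capture, and a 10-subject cohort on a wider-field
96 x 96 x 40 grid at 1.2 x 1.2 x 1.0 mm whose meniscus separation matches
a real plateau; the deformable stage there runs on a region cropped to
the meniscus neighbourhood (6-voxel margin).  These sizes make the whole
validation suite run on a single CPU at desk scale while keeping every
geometric relation (anisotropy, meniscus-to-plateau proportions) intact.

# Known limitations

* **Tangential sliding is not observable.** All stage-2 data terms are
  driven by the meniscus contour (indicator SSD and the mask-distance
  penalty), so a displacement component that slides tissue *along* a
  smooth stretch of its own boundary leaves the data unchanged — the
  classical aperture problem.  Within the meniscus such components are
  filled in by the curvature regulariser, not measured.  Recovery
  validation therefore uses boundary-normal bump fields (amplitude up to
  6 mm at widths giving ~15% peak strain, the physiological regime);
  obliquely directed bumps recover their radial component well but show a
  systematic tangential shortfall.  In vivo, whole-meniscus translation —
  which moves the arch ends and is fully observable — dominates, but
  segment-level AP/ML values inevitably inherit some regulariser
  smoothing along the arch.
* The anatomical-axis sign convention assumes an approximately RAS world
  frame; volumes with strongly oblique orientations will still get a
  consistent plane but the posterior disambiguation relies on the world
  anterior axis.
* The arc-length partition assumes a crescent (C-shape) topology; highly
  irregular or fragmented masks are rejected rather than partitioned.
* `register_deformable` regularises bending only; it does not enforce
  diffeomorphic or inverse-consistent fields.  For the motion magnitudes
  of this application (below ~8 mm over a ~20 mm support) the recovered
  fields are well-behaved, but the solver will not warn about folding.
* Cohort p-values are unadjusted for multiplicity by design; with 48
  cells per comparison grid, isolated small p-values must be read in the
  exploratory sense.
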