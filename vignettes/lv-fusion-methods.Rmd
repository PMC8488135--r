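---
title: "Methods: multi-modality fusion analysis of LV surface models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-modality fusion analysis of LV surface models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvfuse)
```

## The problem

Cardiac magnetic resonance (CMR) and 3D echocardiography (3D-echo) both
produce left-ventricular (LV) surface models — endocardial and epicardial
triangle meshes at end-diastole (ED) and end-systole (ES) — but in
unrelated scanner coordinate systems, with different fields of view and
different systematic errors. To compare them point by point, both models
must be brought into one *cardiac* coordinate system, rigidly registered,
and re-expressed on a common template so that "the same point" is well
defined on both. `lvfuse` implements that fusion chain and the
method-comparison statistics that are usually reported with it, and ships a
synthetic phantom generator so that every stage can be validated against
known ground truth without any patient data.

## The cardiac coordinate frame

The frame is anchored on fiducial landmarks that both modalities can
identify: the apical and basal centroids, which define the LV long axis,
and the right-ventricular (RV) insertion points, which fix the rotation
about that axis. We place the origin at the *basal* centroid (both
modalities delineate the base reliably, and the normalized longitudinal
coordinate then runs 0 at the base to 1 at the apex; the choice of origin
is a package convention). `e_long` is the unit base-to-apex vector;
`e_rv` is the unit component, orthogonal to `e_long`, of the direction
from the origin to the RV centroid; `e_norm = e_long x e_rv` completes a
right-handed triad.

Two landmark conventions are supported. In the CMR convention the RV
centroid is the mean position of all marked insertion points. In 3D-echo
the anterior insertion is usually invisible, so the RV direction is
estimated from the inferior insertion alone, rotated 70 degrees clockwise
as seen by a viewer at the apex looking toward the base. With `e_long`
pointing base-to-apex, that viewer sees a rotation by $-70^\circ$ about
`e_long` (right-hand rule); this algebraic sign is declared once and used
everywhere. Cardiac coordinates of a point are $(u, \phi, r)$: normalized
longitudinal position, circumferential angle from `e_rv` toward `e_norm`
(degrees, $[0, 360)$), and radial distance from the long axis (mm).

A note on handedness: a circumferential layout is only defined up to a
mirror unless it is pinned to patient anatomy. The package pins it by
declaring the sector table below and the $-70^\circ$ sign together; the
phantom generator then places its inferior and anterior insertions at
$\phi = +70^\circ$ and $-70^\circ$, which makes the mean-of-insertions
(CMR) and 70-degree-rule (echo) constructions agree exactly. All
partition logic is self-consistent under this declaration, and every test
of the partition is anchored to it rather than to an external atlas.

## Registration

**Coarse.** Expressing both models in their own cardiac frames and
superposing the frames aligns the long axis and the RV direction; because
the frames are orthonormal triads with a common anchor point this fixes
all six rigid degrees of freedom in closed form (`coarse_align()`).

**Refinement.** The residual misalignment is removed by point-to-point
iterative closest point (ICP) on the union of sampled endocardial and
epicardial points: one-way nearest-neighbour correspondences (ties to the
lowest index) alternating with the closed-form SVD (Kabsch) rigid update,
until the RMS correspondence distance changes by less than `tol` (default
$10^{-4}$ mm) or `max_iter` (100) is reached. Non-convergence warns but
does not abort, and an RMS residual above `rms_threshold` (default 5 mm,
configurable) flags a poor fusion for review — the automated counterpart
of a visual-inspection check. A `manual_override` transform can replace
the refinement for any phase when an analyst has already verified an
alignment by hand.

By default `register_subject()` uses *trimmed* ICP (`trim = 0.85`): each
rigid update uses only the 85% best-matching correspondences. The reason
is scientific rather than numerical: genuine regional shape differences
between modalities (e.g. local echo underestimation of the anterolateral
wall) occupy a minority of the surface, and classic ICP will tilt the
whole rigid alignment to split that difference, shrinking the apparent
regional error and smearing it into neighbouring segments. Trimming
leaves noiseless
whole-surface recovery exact while insulating the pose from localized
disagreement. `trim = 1` restores classic ICP, whose objective is
provably non-increasing.

ED and ES are registered independently, with no shared parameters,
because transducer position relative to the heart can change between the
acquisitions of the two frames.

ICP initialized at identity has a finite convergence basin: on scattered
surface samples it recovers misalignments up to 10 degrees / 10 mm
exactly, but on slice-structured meshes the sampling lattice admits
column-shifted local minima well inside that range. This is why the
pipeline always initializes ICP at the coarse frame alignment, which is
exact up to landmark error.

## The common template and least-squares re-fit

Corresponding points are obtained by re-fitting every surface to one
canonical template: a single-valued radial field $r(u, \phi)$ on a
regular grid of `n_u` longitudinal by `n_v` circumferential nodes
(defaults 24 x 24), periodic in $\phi$, with a fixed u-major node
ordering. The fit solves the linear regularized least-squares problem

$$\min_r \; \sum_j \left(B(u_j, \phi_j)\, r - r_j\right)^2
  + \lambda \lVert D r \rVert^2$$

where $B$ is bilinear interpolation on the periodic grid and $D$ stacks
second differences along $u$ and (periodically) along $\phi$. The system
is sparse and solved exactly; `lambda_smooth` defaults to 1.0, which
suppresses sampling noise below its input level while leaving smooth
anatomy essentially unbiased (a radial-field analogue of thin-plate
smoothing; heavier smoothing monotonically reduces roughness). Grid
nodes without supporting data are filled by the regularizer with a
sparse-coverage warning; with `lambda_smooth = 0` they make the system
singular and raise an error instead.

The template assumes the surface is star-shaped about the long axis
(single-valued radius), which holds for all truncated-ellipsoidal LV
shapes in scope; a pre-check rejects inputs whose radii spread more than
15 mm within one grid cell. Fitted radii are floored at a small positive
value ($10^{-3}$ mm) so the apical ring never degenerates when a surface
closes onto the axis. The mesh is closed at the apex by a pole vertex on
the long axis at $u = 1$; the basal ring is left open, since LV models
are truncated at the base in both modalities. Because the epicardium
extends beyond the endocardial apical centroid, each surface is fitted
with its own longitudinal extent (taken from the reference data and
shared between modalities), and cross-surface operations rescale $u$
accordingly.

Two surfaces fitted on equal grids are in node-wise correspondence by
construction. Whether published surface comparisons use template-node
correspondence or nearest-point matching is often unstated; node
correspondence is the default here (it is symmetric, and it is what
"re-fitted to a common model" implies), and a nearest-point variant is
available as a labelled alternative (`method = "nearest"`), which is
asymmetric and bounded above by the corresponding-node distance.

## AHA partition and regional surface distance

Longitudinal thirds by $u$ (basal, mid, apical) and the apical cap from
`cap_u` (default 0.90 — the cap boundary is not standardized, so it is a
configurable convention and the partition tests do not depend on it).
Circumferential sectors are anchored at `e_rv` (the mid-septum):
basal/mid rings in 60-degree sectors — anteroseptal $[0, 60)$, anterior
$[60, 120)$, anterolateral $[120, 180)$, inferolateral $[180, 240)$,
inferior $[240, 300)$, inferoseptal $[300, 360)$ — and the apical ring in
90-degree sectors (anterior, lateral, inferior, septal, with septal
spanning $[315, 45)$). AHA ids: basal 1-6, mid 7-12, apical 13-16, cap
17. Boundaries are half-open, ties to the lower sector. The endocardium
carries 16 segments (its apical-cap nodes are masked); the epicardium
carries all 17. Labels are computed on the reference (CMR) surface and
applied to both models through node correspondence.

Per segment, the regional error is the mean surface distance

$$MSD_{AHA} = \frac{1}{N_p} \sum_{p=1}^{N_p} d(M_p, E_p),$$

the average Euclidean distance between corresponding points of the
reference model $M$ and the re-fitted test model $E$ over the $N_p$
nodes of the segment. A segment with no nodes is reported as absent,
never as zero.

## Global indices

Cavity volume closes the basal opening with a fan to the basal-ring
centroid and sums signed tetrahedra to the origin (divergence theorem);
the result is orientation-independent and rigid-invariant, and agrees
with analytic solids to a few tenths of a percent at a 48 x 48 grid. LV
mass is shell volume (epicardial minus endocardial) times myocardial
density, 1.05 g/ml by convention (configurable); it is computed from the
ED models. $EF = 100\,(EDV - ESV)/EDV$. Volumes and mass are indexed by
body surface area on request. All methods' volumes are computed on
fitted template surfaces with the same operator, so inter-method
differences reflect geometry, not mesh-processing details.

## Regional signal intensity

Echo image appearance is regionally heterogeneous (systematic anterior
dropout), which the intensity module quantifies. Intensities are
normalized per image between 0 and the 95th percentile (clipped, then
scaled to $[0, 1]$); reported values are percentages of that normalized
peak. The percentile is the inverse-ECDF order statistic rather than an
interpolated quantile: with interpolation, re-normalizing an already
clipped image would find its 95th percentile just below the clipped
block and shift every value, whereas the order statistic makes
normalization exactly idempotent (and returns the same value, 95, on the
canonical 0..100 example).

Sampling happens in the myocardial shell: a voxel centre at cardiac
coordinates $(u, \phi, r)$ is myocardial when
$r_{endo}(u, \phi) \le r \le r_{epi}(u, \phi)$ (radial betweenness, exact
for star-shaped surfaces and fast on regular grids), and it takes the
AHA label of its $(u, \phi)$. Whether published intensity figures sample
the shell or fixed image sectors is typically unstated; the shell is
chosen here because dropout matters exactly where the wall must be
delineated. This is an open modelling choice, recorded as such.

## Agreement statistics

* `paired_t()` — classical paired t on the differences, $n - 1$ df,
  two-tailed, flagged against a Bonferroni-corrected threshold; with the
  default three echo methods compared against CMR, the corrected level is
  $0.05/3$, i.e. two-tailed $P < 0.0167$.
* `icc_a_k()` — McGraw-Wong ICC(A,k): two-way model, absolute agreement,
  average of $k$ measurements,
  $ICC = (MS_R - MS_E)\, /\, (MS_R + (MS_C - MS_E)/n)$. The
  absolute-agreement form is used because a fixed set of methods rates
  every subject and systematic offsets should count against agreement.
* `bland_altman_two()` — bias and 95% limits of agreement,
  $\text{bias} \pm 1.96\,SD$ of the paired differences (sample SD).
* `bland_altman_multi()` — for $k \ge 3$ methods, differences of each
  method from the per-subject mean; per-method biases (summing to zero by
  construction) and one symmetric LoA half-width, $1.96 \times SD$ of the
  pooled bias-removed differences with no small-sample or row-mean
  correlation correction. Pooling after bias removal is what makes the
  half-width estimate $1.96\,\sigma\sqrt{(k-1)/k}$ under i.i.d. noise;
  pooling raw differences would additionally absorb the spread of the
  method offsets themselves. For $k = 2$ the deviations are just
  $\pm$ half the pairwise difference, so the function requires
  $k \ge 3$ and two-method comparisons use `bland_altman_two()`.

## The phantom generator

`make_phantom()` builds a truncated-ellipsoid endocardium (semi-axes
$a, b, c$; base plane a fraction $\tau$ of $c$ below the centre) with an
epicardium offset by the wall thickness (semi-axes grown by $t$, same
centre, same basal plane), smooth on purpose: papillary muscles and
trabeculae are excluded from the myocardium in the contouring convention
being emulated, and echo-style underestimation is modelled as an explicit
inward regional deformation (`apply_regional_bias()`), not as simulated
trabeculae. Default anatomy: $a = b = 28$, $c = 52$ mm, $\tau = 0.5$,
9 mm wall — an end-diastolic cavity of about 144 ml, in the range of a
healthy adult. ES is derived from ED by scaling radii about the long
axis by $\sqrt{1 - EF}$ (a linear map of determinant $1 - EF$, so the
target EF, default 60%, is met exactly on the continuous solid and on
the discretized mesh alike), with the epicardium rescaled to conserve
wall volume. This is a kinematic, not mechanical, model of systole: it
produces correct volumes and distinct per-phase poses, which is all the
registration and volumetry stages require.

Landmarks are placed analytically (apex pole, basal-ring centroid,
insertions on the epicardial base ring at $\pm 70^\circ$). The echo copy
of each phase is displaced by a ground-truth rigid transform with fixed
magnitudes and seeded random directions. Surface sampling is
slice-structured (rows of constant height), like contour stacks, with an
aperiodic golden-ratio stagger between rows so the sampling lattice does
not manufacture symmetric local minima for registration experiments.
Optional radial Gaussian noise is applied to the echo side only. Every
quantity is reproducible bit-for-bit from (spec, seed); cohort subjects
get independent streams derived from the cohort seed.

`make_echo_volume()` voxelizes the phantom (default 1 mm isotropic) with
piecewise-constant per-segment shell intensities, a dim blood pool and
near-zero background — the circumferential dropout structure of 3D echo.
It also paints a small deterministic population of peak-intensity voxels
(just over 5% of the grid, standing in for the bright clutter every real
echo image contains) so that the per-image 95th-percentile normalization
lands exactly at the intended peak; without such a bright tail, the 95th
percentile of a shell-plus-background phantom would fall inside the
shell's own intensity distribution and distort every target on
round-trip. Multiplicative speckle can be added to tissue voxels.

The deformation window of `apply_regional_bias()` carries full amplitude
across the target segment's $(u, \phi)$ box with a raised-cosine decay
outside it (defaults: 10 degrees angular, 0.05 longitudinal), so the
segment-mean displacement stays close to the nominal amplitude; optional
insets shrink the box for experiments that need the deformation strictly
interior to one segment — relevant because template nodes sit exactly on
sector boundaries, where any window that covers its own segment must also
displace the shared boundary node.

What the phantoms do *not* emulate: trabeculated endocardium, real
speckle texture and shadowing, landmark identification error, non-rigid
beat-to-beat deformation, and tool-specific contouring behaviour.
Passing phantom tests therefore demonstrates that the pipeline's
geometry, statistics and bookkeeping are correct, not that any particular
clinical accuracy will be achieved on patient data.

## Numerical choices and problem sizes

Geometric identities are asserted at $10^{-9}$ (angles internally in
radians, reported in degrees; lengths mm, volumes ml, mass g).
Nearest-neighbour ties resolve to the lowest index; sector-boundary ties
to the lower sector. Registration point sets are subsampled
deterministically (evenly strided) to at most 800 source / 2000
reference points, which bounds the ICP cost without materially affecting
the pose. The validation suite runs phantoms of 800-2400 points with
24 x 24 templates (48 x 48 where volumetric accuracy is measured), and
the cohort-scale checks use 20-100 subjects; these sizes keep the full
suite in the order of a minute on one core while leaving every tolerance
comfortably resolved.

## Known limitations

Rigid registration only (by design — non-rigid fusion is out of scope);
star-shaped surfaces only; the basal cap is a flat fan at the basal-ring
plane; node correspondence inherits any bias of the template
parameterization near the apex pole; the multi-method LoA deliberately
omits the $\sqrt{k/(k-1)}$ inflation that would account for row-mean
correlation, matching the plain pooled-SD description it implements; and
the AHA sector anchoring, while fully self-consistent and configurable,
is a declared convention rather than a reproduction of any specific
atlas implementation.
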