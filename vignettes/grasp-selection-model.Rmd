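---
title: "A normative model of two-digit grasp selection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A normative model of two-digit grasp selection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graspsel)
```

## The model in one paragraph

A two-digit grasp is an ordered pair of contact points — thumb and index —
on the accessible surface of a rigid object. Discretizing the surface at
triangle centers turns the space of grasps into a finite 2D manifold (an
N × N table under a shared candidate ordering), over which five cost
functions are evaluated, each normalized to [0, 1] per object, and summed.
The minima of the combined map are the grasps that best satisfy all the
constraints simultaneously; predicted grasps are sampled from around those
minima. The model assumes a rigid object of known geometry and mass
distribution resting on a table, a two-digit precision grip with
point-like contacts, and a seated actor whose hand approaches from a known
start location.

## The five penalties and their assumptions

**Force closure.** The grasp axis must align with the directions along
which the digits can push, the inward surface normals. The penalty is the
sum of the two angular deviations, computed as
`atan2(‖F × a‖, F · a)` with `F = −n` and `a` the grasp axis, range
[0, 2π] rad. This is a frictionless idealization: friction cones would
widen the set of zero-penalty grasps by a material-dependent angle, which
the model deliberately omits (normalization makes the maps
unit-free, so only the shape of each cost matters).

**Torque.** Assuming each digit applies a force countering gravity at its
contact, the residual torque about the contacts is
`‖(CoM − CP_T) × (−F_g) + (CoM − CP_I) × (−F_g)‖` (N·m). Because gravity
is vertical, only the horizontal offset of the contact *midpoint* from the
CoM matters: the map is zero on the set of pairs whose midpoints lie on
the vertical line through the CoM. The printed formula counts the full
counteracting force per digit; whether each digit should carry half is
ambiguous in the source and irrelevant after normalization (it scales the
map by 2). The formula is implemented literally.

**Natural grasp axis (NGA).** Humans prefer a particular orientation of
the thumb-to-index axis, determined by arm biomechanics; the default
direction `[0.49, 0.87, 0]` comes from a published regression of preferred
postures for this seating geometry and is unit-normalized on load (its
printed norm is 0.9985). The penalty is the angle between grasp axis and
NGA, range [0, π]. It is the only asymmetric map: swapping digits reverses
the axis, so `P(i,j) + P(j,i) = π`.

**Grasp aperture.** Zero up to 25 mm thumb–index distance, then linear in
the excess (mm). The threshold reflects the object size at which humans
abandon two-digit grips; the boundary point (exactly 25 mm) is assigned
zero penalty, consistent with both branches of the printed definition.

**Visibility.** The hand occludes the part of the object on its side of
the grasp: contacts and all candidate surface points are projected to the
horizontal plane, and the penalty is the fraction of points strictly on
the side of the 2D grasp line containing the hand start location. Points
exactly on the line (including the contacts) count as visible. The source
prints this function under a colliding label and describes it once as the
"proportion still visible"; it is implemented as the *occluded* fraction,
since a penalty must grow with occlusion. Occlusion is counted per
candidate point, not per unit area.

## Combination, normalization, prediction

Each raw map is min–max rescaled over its unmasked entries, per object. A
constant map rescales to all zeros: a cost that cannot discriminate
between grasps should contribute nothing. The diagonal (both digits on the
same triangle) is masked as physically impossible. The unweighted model
sums the five normalized maps and rescales to [0, 1]; the fitted model
uses `Σ w_i P_i²`. The squared form follows the printed fitted model; a
reading in which the exponent is a typographical artifact is supported via
`combine_maps(..., squared = FALSE)` and
`fit_weights(..., squared = FALSE)`.

Predictions keep the grasps at or below the lower 0.1th percentile of the
combined map (about 0.1 % of grasp space, matching the share humans cover)
and sample n grasps with replacement with probability `1 − penalty`,
renormalized over the survivors. The survivor set always contains the map
minimum, for any positive percentile.

## Weight fitting

Observed grasps are snapped to their nearest candidates and define
`P_H` (0 at selected pairs, 1 elsewhere). The regularization table R
equals the selection count at selected pairs and
`N_selected / N_nonselected` elsewhere, so each region's R sums to
`N_selected`. Weights in [0, 1], started at 0.2, minimize the weighted
misfit to `P_H`.

Two decisions here deserve comment:

* **Where R enters.** The printed objective squares the product
  `R · (Σ w_i P_i² − P_H)`, which weights regions by R² and collapses the
  non-selected region's total influence to `N_sel²/N_nonsel` — defeating
  the explicitly stated purpose of R (equal importance of both regions).
  The default therefore minimizes `Σ R · (residual)²`, which realizes the
  intended balance exactly; on synthetic observers it recovers weight
  rankings well (mean Spearman ρ ≈ 0.87 in the acceptance suite) where the
  literal form plateaus near 0.62. The literal form remains available as
  `residual_weighting = "literal"`.
* **Solver.** The residual is linear in w, so the problem is a
  box-constrained convex quadratic program: any bounded descent method
  reaches the global optimum. It is solved with `stats::nlminb` (projected
  quasi-Newton, analytic gradient, tolerances 1e-10); a trust-region
  least-squares routine would return the same minimizer. Relative weights
  are defined as `w_i / Σ w_j`.

## Similarity and behavioral statistics

Similarity is `100·(1 − ‖G₁ − G₂‖ / D_max)` with the 6D grasp vectors and
`D_max` the largest pairwise 3D vertex distance of the object. Because a
6D distance can exceed the 3D extent, similarity can be negative; values
are reported unclamped (an optional floor at 0 exists) so that means are
not biased upward. The medoid of a grasp set minimizes summed 6D distance,
ties broken to the lowest trial index. Chance similarity is the mean
similarity of uniformly random candidate pairs to their own medoid, with a
seeded bootstrap CI. The CoM distance of a grasp is measured from the
thumb–index *midpoint* (the source does not state the reduction; midpoint
matches the torque structure). Spatial bias is measured in 3D by default,
with a planar mode. Egocentric encoding keeps participant-frame
coordinates; allocentric encoding maps contacts through the inverse object
pose.

## Synthetic data: what the generators state, and what a green test shows

* `build_polycube` regenerates the stimulus family: 2.5 cm cubes, per-cube
  masses 9.7 g (wood) and 133.5 g (brass), calibrated so the printed
  totals are exact (10 wood = 97 g; 5 + 5 = 716 g). The independently
  printed familiarization rods imply 10 g / 134 g per cube, within 4 % of
  these defaults. The exact L/U/S/V cube arrangements are not derivable
  from the source renderings; the shipped layouts are plausible
  reconstructions (two standing, two flat) and are marked as such, so
  published CoM-shift statistics are not certified anywhere in the
  package.
* `simulate_observer` samples trials from a weighted map with known
  `w_true` through the same truncation/resampling rule as predictions,
  optionally jittering contacts within the k nearest candidates. It
  contains no reach kinematics, no motor noise model beyond that jitter,
  and no learning across trials.
* `simulate_clustered_grasps` draws a population anchor pair, per-subject
  centers around it (σ_between, default 15 mm), and trials around centers
  (σ_within, default 5 mm — the scale of human repeat-grasp scatter).
  These defaults state the world in which the within > between > chance
  ordering is expected and tested.

A green acceptance suite therefore establishes that the implementation
realizes the stated model on its stated synthetic world — not that the
model fits any particular human dataset.

## Numerical choices

* Coordinate frame: x rightward, y away from the participant, z up, table
  at z = 0 (the source never states axes; this choice makes transverse =
  about z and sagittal = about x rotations expressible). The hand start
  default is (280, 95, 0) mm, from the printed seating geometry.
* Table-contact exclusion: faces with all three vertices within 1 mm of
  the table plane (no tolerance is printed).
* Contact snapping uses nearest triangle centers (consistent with the
  manifold discretization, not exact surface projection); snaps beyond
  20 mm are flagged as suspect.
* Mesh resolution: 128 triangles per exposed cube face reproduces the
  original stimulus meshes; tests and the acceptance script run at 2–8
  triangles per face (16–304 candidates) because map construction is
  O(N²) in memory and the visibility map O(N³) in time. At 5376
  candidates the five maps alone occupy ≈ 1.4 GB.
* Degenerate visibility pairs (contacts projecting to the same 2D point)
  fall back to the line through the point perpendicular to its hand
  direction, with a logged message.
* Identity-level perturbations mutate the configuration in place rather
  than rebuilding it, so they reproduce the baseline bit-exactly under a
  fixed seed.
* `g` = 9.81 m/s²; raw torque maps carry N·m for interpretability, though
  units cancel under normalization.

## Known limitations

Frictionless force closure; point contacts (no pads or patches); two
digits only; no reach-length cost (a documented near-equivalent of
visibility in the source setting); no trajectory or hand-kinematic model;
mesh quality is the caller's responsibility (open meshes fall back to
surface centroids with a warning, and only ASCII mesh files are read).
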