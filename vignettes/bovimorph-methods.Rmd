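---
title: "Models and methods behind bovimorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bovimorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices in
`bovimorph`: what is modelled, why the defaults are what they are, and
what passing the test suite does and does not demonstrate about real
animals.

## The measurement problem

Morphological phenotyping of dairy cattle from 3D scans follows a fixed
chain: a rig of depth cameras captures the standing animal in one shot;
the depth maps are fused into a watertight triangulated mesh; an operator
clicks anatomical feature points on the mesh; geometric computations turn
mesh and points into traits (heights, widths, girths, surfaces, volumes);
linear equations convert partial measures to whole-body measures and
predict body weight. The quality of such a device is summarised by
repeatability (same acquisition, repeated point identification),
intra-facility reproducibility (separate acquisitions of the same animal
in a changing environment), and agreement with a reference device.

`bovimorph` implements every computational stage of that chain and, since
scans of real animals are not distributable, pairs it with a synthetic
animal model rich enough to exercise each stage with known ground truth.

## The body model

A cow is an implicit solid, the smooth union (polynomial smooth-minimum,
blend radius 0.03 m) of:

* a **torso**: lofted superellipsoid with half-axes
  `torso_half_length` (0.84 m), `torso_half_width` (0.29 m),
  `torso_half_height` (0.405 m) and a cross-section/profile exponent pair
  (default 0.5 / 0.25, i.e. a rounded-square section and a blunt-ended
  profile; 1 / 1 recovers an ellipsoid exactly);
* four **legs**: vertical capped cylinders (radius 0.06 m) tapering
  toward the hoof; the hind pair slants backward toward the ground by
  0.2 x torso-half-height, as real cannon bones do — this also makes a
  cross-section through the lower hind legs yield leg contours separate
  from the torso contour;
* an optional **neck + head** capsule with a pitch angle, a **tail**
  capsule, an **udder** ellipsoid, and a **withers bump** at the shoulder
  plane;
* a fine-scale **surface detail** field (product-of-sines corrugation,
  amplitude 12.5 mm, wavelength 0.12 m) standing in for the folds, joint
  detail and reconstruction texture that give real body scans their
  surface area. A smooth geometric primitive of realistic volume falls
  well short of a real cow's surface-to-volume ratio; the corrugation
  closes most of that gap while leaving volumes and linear traits nearly
  untouched.

The zero level set is triangulated by **marching tetrahedra** on a
regular grid (spacing `0.08 / mesh_resolution` metres; the default
resolution 4 gives 2 cm voxels). The Kuhn six-tetrahedron subdivision is
conforming across cube faces and every iso-vertex is keyed by its grid
edge, so the mesh is watertight by construction; triangle winding is
fixed combinatorially (tetrahedron parity times permutation parity),
which is robust where gradient-based orientation heuristics fail on
aliased fields. Exact zeros of the field are nudged by 1e-12 so signs
are always defined.

Default dimensions were calibrated once so that a 16-animal fleet drawn
from the adult preset lands within 10% of published adult-herd means for
surface, volume, withers height, widths, chest depth and abdominal
circumference; the heifer preset is the adult preset scaled uniformly so
that total volume matches a growing-heifer cohort (about 581 L). After
calibration the defaults were frozen; they are parameters of the model,
not fitting knobs.

Ground-truth traits (`true_traits`) use closed forms where they exist
(ellipsoid volume, chest depth, elliptic girths via adaptive quadrature)
and otherwise a reference mesh at twice the working resolution.

## Landmarks and the noise model

Nine landmarks (withers, hips, pins, shoulder tips, buttock tips) and
four cutting stations are placed deterministically from interpolated
section contours of the mesh, which makes them insensitive to mesh
resolution. Stations are stored as pseudo-landmark anchor points, so a
rigid motion of mesh plus landmark file transforms everything
consistently.

Measurement noise has two layers with distinct roles:

* **click jitter** (`click_jitter_sd`, default 6 mm, isotropic): the
  operator's re-identification error. It perturbs landmark coordinates
  and station anchors only — never the mesh — and drives repeatability.
* **posture variation** (`posture_pitch_sd` 0.03 rad on the head,
  `posture_shift_sd` 8 mm on the stance, plus a lever coupling of 0.15
  from head pitch to whole-body pitch): applied once per acquisition
  session, regenerating the mesh, and drives reproducibility. The lever
  coupling reproduces the known sensitivity of withers height to head
  position (a fully raised versus lowered head shifts WH by several
  centimetres).

The defaults were chosen once so that simulated repeatability CVs sit
below 2% and reproducibility CVs dominate them, with every trait under
the 4% quality threshold — the magnitude regime reported for real
devices. Two caveats are documented rather than hidden: the relative
ordering of per-trait CVs does not match a human operator (girths are
nearly insensitive to isotropic jitter, whereas human tape-path choices
are not), and session-to-session posture change affects widths only
weakly, so for width traits reproducibility exceeds repeatability only
in expectation.

In generated study tables, complete volume and surface are derived from
the partial measures through the published conversion equations, so
point-identification noise propagates into them as it does in the real
workflow; the direct mesh values remain available via `measure_all`.

## Trait definitions and geometry kernels

* **WH** is the height of the withers landmark above the ground plane
  (the lowest mesh point in the landmark-derived body frame) — robust to
  the poorly reconstructed legs that plague real scans.
* **CD** is the vertical extent of the torso contour at the chest
  station; **HG**/**AC** are convex-hull perimeters of the torso contour
  (a taut tape bridges concavities; the raw contour length is attached
  for diagnostics).
* **PV/PS** clip the body between planes at the shoulder-blade tips and
  the rump. Clipping caps each opening with a centroid fan whose winding
  is inherited from the directed cut edges of the kept polygons; where
  the plane grazes a surface fold the two directed cut edges cancel and
  no cap is placed, which keeps the result watertight even on corrugated
  bodies. A cut that still fails (contour pinched exactly at the plane)
  is retried with a 1.5 mm plane nudge. Partial surface includes the cap
  discs, i.e. it is the total surface of the clipped solid.
* **Volume** is the signed divergence-theorem sum; it refuses
  non-watertight input with an open-edge count rather than returning a
  biased number. Cross-section chaining splits figure-eight contours at
  revisited vertices so downstream code always sees simple loops.
* Exact anatomical stations are not standardised across devices; they
  are exposed as fractions of body length (defaults: rump 0.04, abdomen
  0.45, chest 0.66, shoulder 0.86) and the heart girth, whose station is
  the least standardised, is excluded from device-comparison defaults.

## The capture simulator

The real device's active-stereo matching is abstracted away: depth maps
are ray-cast directly (projective z-depth, matching consumer RGB-D
convention), then degraded by quantization (`quant_step`, default 2 mm —
the staircase effect) and optional Gaussian noise. The spec of the
smoothing step is a contract, not an algorithm: the bilateral filter
(radius 4 px, range sigma 6 mm) must cut the staircase RMS on planar
regions by at least 3x while moving a 0.1 m step edge by less than 1 mm
and leaving the validity mask untouched.

The default rig has 15 cameras (848x480, ~65 degree FOV): five per side
(floor-level cameras see the belly and the inner faces of the opposite
legs under the torso; high flank cameras; a low frontal camera for head
and jaw) and five overhead including end-on views of rump and face. The
geometry is a declared assumption — the real rig's poses are not public —
and was arranged so that at least 99% of the default adult body surface
is sampled within 1 cm; the remaining fraction is dominated by the
ground-contact hoof soles and the groin, which no external rig can see.

Extrinsics come from checkerboard pairs via the Kabsch algorithm, with a
condition check that rejects collinear corner sets. Fusion concatenates
the posed clouds with 5 mm voxel de-duplication.

**Reconstruction** is an implicit point-set-surface method: on a regular
grid (default 1 cm; 1.25 cm in the full-body tests) the field is the
inverse-distance-weighted mean of signed tangent-plane distances to the
k = 8 nearest cloud points, found through a voxel hash near the surface
and an expanding-ring search over an 8-voxel-downsampled cloud far from
it (far nodes only need the correct sign, and deriving it from the data
itself avoids sign leakage through coverage holes). The outermost grid
layer is forced outside so the level set always closes; a 98th-percentile
surface-to-cloud distance gate (six voxels) then rejects reconstructions
that hallucinated surface in uncovered regions — a hemisphere cloud fails
with a structured `reconstruction_error` instead of returning a silently
wrong mesh. Screened Poisson reconstruction, which production systems
use, is out of scope; the implemented method satisfies the same fidelity
contract (sphere volume within 2%, full chain within 3%).

## Statistics

Repeatability and reproducibility both reduce to the residual SD of the
one-way ANOVA with the animal as factor (computed via `stats::lm`;
`sqrt(SSR / (N - k))`, unbalanced designs allowed), which removes the
morphological variation between animals. CV% is 100 sigma / mean with
the mean taken from the population actually used in that assessment —
the repeatability and reproducibility panels are different animals, so
means are never shared. The 95% limit uses the exact Gaussian
two-determination quantile 1.959964 x sqrt(2) = 2.7718 rather than the
rounded 2.8 of the standards literature, because the defining statement
is the probability, not the constant. The reported `error` column is
sigma itself, which is how published error columns relate to their CV
and mean columns. Traits are analysed independently with no multiplicity
correction. The quality verdict is CV < 4%.

The reproducibility design follows the arithmetic of the published
record counts (8 animals x 5 sessions x 5 identification repeats = 200),
which conflicts with the accompanying prose ("one time by the same
operator"); both designs are expressible.

## Prediction equations and units

All equation math is SI (m^3, m^2, m, kg); litres exist only at the
reporting layer (1 m^3 = 1000 L, exact round trip). The total-volume
intercept 0.015 is only dimensionally sensible in m^3 (15 L, the scale
of a head-plus-neck correction), which fixes the unit convention. In the
body-weight equation HW is hip width, not withers height; named
arguments enforce this. Coefficients are immutable defaults; overriding
them is possible but flagged in output metadata.

## Device comparison

Relative differences are reported as percentages of the reference-device
mean. Regressions are ordinary least squares of test on reference,
matching how device-comparison plots are usually drawn (errors-in-
variables alternatives are deliberately out of scope). Swapping the
devices negates differences and inverts the slope on noise-free data — a
tested symmetry. The comparison defaults to WH, HW, WB, CD, AC, TV and
TS.

## Problem sizes and determinism

The test suite runs the geometry oracles at 2 cm mesh resolution, the
fleet calibration with 16 animals at 2.7 cm resolution, study-design
properties with 2-8 animals at coarse (5-7 cm) resolution over up to 25
seeds, and the full capture chain once at the rig's native 848x480 on a
2.7 cm source mesh — sizes chosen so the whole suite completes in a few
minutes while every contract is exercised at its stated tolerance. All
random draws derive from fixed or caller-supplied seeds; per-record
seeds are split deterministically from the master seed, so studies and
pipeline outputs are byte-reproducible.

## Limitations

* The synthetic animal is a stylised solid: no breed differences, coat,
  body-condition variation, ears/horns, or gait; its surface detail is a
  stationary corrugation, not anatomically placed folds. Passing tests
  shows the *machinery* is correct at realistic scales, not that the
  generator reproduces any particular animal.
* Landmark placement is deterministic-geometric; automatic anatomical
  landmark detection on real scans is explicitly out of scope.
* The stereo-matching physics (IR pattern, sunlight interference,
  USB-bandwidth artifacts) is not modelled; quantization plus Gaussian
  noise stand in for the net depth error.
* Published herd-level table values (exact CVs, device-comparison means,
  regression statistics on real cows) depend on animals that are not
  available; they are covered qualitatively by the synthetic-fleet
  calibration checks, and the worked arithmetic that connects them is
  reproduced exactly.
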