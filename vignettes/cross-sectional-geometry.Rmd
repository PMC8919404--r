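---
title: "Cross-sectional geometry of segmented 3D structures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-sectional geometry of segmented 3D structures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xsection)
```

## The problem

How well a beam-like biological structure — a limb bone, a jaw, a fin spine —
resists bending depends not only on how much material it contains but on how
that material is arranged around the bending axis. The classical summary of
that arrangement is the second moment of area,

$$I_{NA} = \int x^2 \, dA,$$

the integral over the cross-section of squared distance $x$ from the neutral
axis (the line of zero bending stress, which for a centroidally loaded beam
passes through the section centroid). Within Euler–Bernoulli beam theory the
tip deflection of a cantilever under an end point load is
$\delta = FL^3 / (3EI)$ and that of a simply supported beam loaded at midspan
is $\delta = FL^3 / (48EI)$, so $I$ enters comparisons of stiffness on equal
footing with material ($E$), load ($F$) and length ($L$).

Biological cross-sections are irregular, so closed-form $I$ formulas for
canonical shapes do not apply. Given a segmented micro-CT volume, `xsection`
iterates slice-by-slice along a chosen axis and computes, for every
cross-section: area (CSA), centroid, the full centroidal inertia tensor,
second moments about the principal axes and about a user-chosen neutral
axis, section moduli, polar moment of inertia, maximum Feret diameter,
perimeter, mean voxel brightness, total area including internal vacuities,
and compactness — plus length- and material-normalized variants of the
size-dependent quantities, and beam-theory validity checks.

## The per-pixel model

Every foreground pixel is modelled as a solid $p_x \times p_y$ rectangle
centred on its lattice point. The second moment of an arbitrary
cross-section about a centroidal axis is assembled by the parallel-axis
theorem:

$$I_{NA} = \sum_{k=1}^{n} \left( I_{NA',k} + A_k D_k^2 \right),$$

where $I_{NA',k}$ is the rectangle's own moment about the parallel axis
through its centre ($p_x p_y^3/12$ about the horizontal axis), $A_k = p_x
p_y$ its area, and $D_k$ the perpendicular centroid-to-pixel distance. The
exact-rectangle own term makes single-pixel and coarse-grid sections
principled rather than degenerate: one isolated pixel at unit spacing has
$I_{xx} = I_{yy} = 1/12$ mm⁴, exactly the closed form for a unit square.

The moment about a centroidal axis at angle $\theta$ (counterclockwise from
the slice's horizontal, +y up) follows from the tensor rotation

$$I(\theta) = I_{xx}\cos^2\theta + I_{yy}\sin^2\theta
  - 2 I_{xy}\sin\theta\cos\theta,$$

applied separately to the parallel-axis part and to the (product-free)
rectangle own terms. The test suite verifies this against a literal
per-pixel re-summation at random angles to $10^{-9}$ relative tolerance,
and checks the exact identities $J = I_{xx} + I_{yy}$ (perpendicular-axis)
and $I_{\text{offset}} = I_{\text{centroidal}} + A d^2$ (parallel-axis).

Principal axes are the eigenvectors of the 2×2 tensor. Following the
comparative-biomechanics convention, $I$ about the *minor* principal axis
is the maximum (highest bending resistance) and $I$ about the *major* axis
the minimum; `theta_principal` reports the major (minimum-$I$) axis angle
in $(-90°, 90°]$, with 0° as the tie-break for isotropic sections. The
user-supplied neutral-axis angle is held constant across all slices of a
run, whereas the principal axes rotate freely from slice to slice; both
axes always pass through the slice centroid — non-centroidal neutral axes
(relevant to end-loaded beams) are out of scope.

## Derived per-slice quantities

* **Section modulus** $Z = I(\theta)/c$, with $c$ the largest perpendicular
  distance from the axis to a foreground *pixel centre*. The centre
  convention (rather than pixel corners) matches the per-pixel model; a
  degenerate section lying entirely on the axis has $c = 0$ and yields a
  flagged `NA`.
* **Polar moment** $J = I_{xx} + I_{yy}$, the torsion analogue.
* **Maximum Feret diameter**: the greatest caliper distance, computed as
  the maximum pairwise distance between convex-hull points of the
  boundary-pixel *corners* (so a single pixel measures its diagonal,
  $\sqrt{2}$ mm at unit spacing). Corner-based calipers carry a positive
  bias of up to about one pixel pitch.
* **Perimeter**: the length of the 0.5-level marching-squares isocontour.
  On a raw binary field every edge crossing sits at an edge midpoint and
  the staircase overestimates smooth boundaries by ~5% regardless of
  resolution, so the field is first smoothed with a 3×3 mean filter,
  letting the linear interpolation place crossings sub-pixel; the residual
  error on discs and rectangles is under 1%. Features thinner than about
  two pixels vanish under smoothing, so such sections fall back to the
  unsmoothed contour.
* **Vacuities and compactness**: total cross-sectional area (TCSA) adds to
  the foreground every enclosed background region — background components
  not connected to the slice border under 4-connectivity (8-connectivity
  for foreground, the standard dual pairing that avoids topological
  paradoxes). Compactness = CSA/TCSA ∈ (0, 1]; a notch open to the border
  is not a vacuity. Hole filling is delegated to `EBImage::fillHull()`.
* **Mean brightness**: the arithmetic mean of the co-registered intensity
  volume over foreground pixels only; `NA` when no intensity volume is
  supplied.

Slices inside the occupied range that contain no foreground (e.g. a
segmentation gap) are kept as `NA` records so row indices stay aligned with
the volume; they are excluded from plots and from the Feret minimum. By
default all foreground components in a slice are measured together; the
`largest_island` option restricts to the largest connected component for
fragmented segmentations.

## Normalizations

Two normalizations support comparisons across differently sized structures:

* **Length normalization** reduces each property to a dimensionless linear
  measure: $I^{1/4}/L$, $Z^{1/3}/L$, $J^{1/4}/L$, $\mathrm{CSA}^{1/2}/L$.
  It is exactly invariant under isometric scaling. $L$ defaults to the
  occupied extent along the slicing axis (slice count × slice spacing); an
  override accommodates anatomical length definitions (e.g. between
  landmarks that the segmentation does not span).
* **Material normalization** divides $I$, $Z$ or $J$ by the value for a
  solid circle of equal area ($r = \sqrt{\mathrm{CSA}/\pi}$, so
  $I_\circ = \mathrm{CSA}^2/4\pi$, $J_\circ = \mathrm{CSA}^2/2\pi$,
  $Z_\circ = \mathrm{CSA}^{3/2}/4\sqrt{\pi}$), isolating the effect of
  shape: a thin-walled tube scores well above 1 because its material sits
  far from the axis, and a rasterized solid disc converges to exactly 1
  with refinement.

No normalization isolating cross-section *size* alone is provided: choosing
a size proxy (width, area, perimeter …) is shape-dependent and ambiguous
for irregular sections.

## Alignment and slicing

Cross-sections are meaningful only perpendicular to the structure's long
axis. The automatic mode eigen-decomposes the covariance matrix of
foreground voxel-centre coordinates; the largest-variance eigenvector (the
axis of smallest moment of inertia — the long axis) is mapped to the
slicing axis. The mask is unweighted: density weighting of the alignment
(like density-weighted moments generally) is deliberately not implemented,
because it requires calibrated grayscale values that most public CT scans
lack. Determinism is enforced by (a) snapping tied eigenvalue groups to the
nearest coordinate axes, so cubes and already-aligned boxes return the
identity; (b) a sign rule (non-negative projection on z, then x, then y);
and (c) recomputing the third axis as a cross product, guaranteeing a
proper rotation. Rasterization tests recover generated tilts of 10–45°
to within 0.2° at a voxel pitch of 1/40 of the beam length.

Explicit rotations use Euler angles applied in the fixed order x, then y,
then z, about the foreground centroid by default. Masks are resampled with
nearest-neighbor interpolation (labels stay binary) on an output grid
expanded so no foreground is clipped, with the output lattice phase-aligned
to the transformed input lattice so that lattice-preserving rotations (90°
multiples at isotropic spacing) are exact voxel permutations; intensity
volumes follow the same transform with trilinear interpolation. Oblique
resampling loses of order 1% of voxels to rasterization at typical pitches,
which is why readers reject obliquely oriented native grids rather than
silently resampling them.

Percent length of plane $i$ in the occupied range $[i_{first}, i_{last}]$
is $100 (i - i_{first})/(i_{last} - i_{first})$, defined as 0% for a
single-plane structure.

## Beam-theory validity checks

Euler–Bernoulli results are trustworthy only for slender beams with small
deflections. The package computes, per run: the aspect ratio $L / \min
\mathrm{Feret}_{max}$, where the minimum is taken after dropping
$\lfloor 0.05\, n \rfloor$ occupied slices at each end (no trimming below
20 slices) to keep flared epiphyses or ragged ends from defining the
width; a shear warning when the ratio is strictly under 10 (a ratio of
exactly 10 passes); and, in the deflection calculator, a small-deflection
flag that is `TRUE` exactly when $\delta < 0.10 L$. The 5% trim counts
slices, not physical length.

## Synthetic fixtures and what passing tests show

The generator rasterizes canonical beams — cylinder, tube, box, elliptical
beam, I-beam, obliquely tilted cylinder, and a gapped dumbbell — by marking
voxels whose centres fall inside the continuous solid, with no partial
volume, deliberately matching the binary pixel model of the engine so that
discretization errors are consistent between fixture and measurement.
Closed forms ($\pi r^4/4$, $\pi(r_o^4 - r_i^4)/4$, $wh^3/12$,
$\pi a b^3/4$, composite-rectangle sums for the I-beam, Ramanujan's
approximation for the ellipse perimeter) provide the ground truth. At a
pitch of 1/100 of the smallest feature every metric lands within 1% of its
closed form (2% for perimeter); errors shrink with refinement, modulated
by grid-phase noise at any single pitch.

These fixtures emulate the *geometry* of real data: arbitrary cross-section
shapes, internal vacuities, anisotropic voxels, oblique orientation, gaps.
They do not emulate segmentation noise, partial-volume boundary blur,
density heterogeneity, or curved beam axes — so passing tests certify the
geometry engine, not robustness to imperfect segmentations, which remains
the user's responsibility at segmentation time.

## Problem sizes and numerical choices

The shipped test-suite and validation runs use sections up to about
1000×1000 pixels and stacks of a few hundred slices, which keeps the whole
suite under a minute on a single core while placing discretization errors
well inside the stated tolerances; all computations are vectorized
summations and scale linearly in foreground pixel count. Isotropy
tie-breaks trigger when $|I_{xx} - I_{yy}|$ and $|I_{xy}|$ are below
$10^{-12} J$; eigenvalue ties in 3D alignment below a $10^{-6}$ relative
gap. NRRD files are written with raw little-endian encoding and exact
(17-digit) spacing so integer volumes round-trip bit-exactly; NIfTI spacing
passes through the format's float32 header field, exact only to ~$10^{-7}$
relative. TIFF stacks carry no spacing metadata and default to 1 mm with a
warning.

## Known limitations

* Neutral axes are centroidal only; end-loaded beams shift the neutral
  axis toward the tensile side and need experimental data to locate it.
* No density weighting of moments or alignment (uncalibrated grayscale).
* Straight slicing axis only: no centerline/curved-axis slicing.
* The corner-based Feret caliper and centre-based section-modulus distance
  each carry ~one-pixel biases of opposite sign; at recommended pitches
  (feature/50 or finer) both are below 1–1.5%.
* Perimeter of structures thinner than ~2 pixels falls back to the binary
  contour, which underestimates such features.
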