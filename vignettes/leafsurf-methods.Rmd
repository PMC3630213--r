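---
title: "Reconstructing curved leaf surfaces from focus stacks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing curved leaf surfaces from focus stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafsurf)
```

# Why a 3D model

Young leaves are bent, so the 2D Euclidean distance between two epidermal
points on a micrograph underestimates their true separation on the surface,
and the bias varies locally with the leaf's curvature. Any comparison of
trichome spacing or density between genotypes that ignores this conflates
patterning differences with shape differences. The package therefore
reconstructs the surface from an ordinary bright-field focus series and does
all spatial statistics on (or relative to) that surface.

# The pipeline, stage by stage

## Shape from focus

Each surface point is in focus in the slice whose focal plane matches its
height. Sharpness is measured per slice as the Sobel gradient magnitude with
the standard 3×3 kernel pair and edge-replicated borders; a pixel's aggregate
sharpness is the maximum of that measure over a `window × window`
neighborhood (default 5, the classical choice for this measure), which makes
the argmax robust to locally textureless pixels next to textured ones. Ties
in the argmax go to the lowest slice so output is order-stable. Pixels with
no texture anywhere (aggregate sharpness `< texture_eps` in every slice)
inherit the height of the nearest textured pixel by breadth-first
propagation; the elastic map later smooths the residual noise.

The axial scale cannot be read from the microscope: it is calibrated from a
cover-slide fragment of known thickness imaged next to the leaf
(`calibrate_z(thickness, idx_bottom, idx_top)` = thickness / |Δindex|). The
lateral scale (µm/px) is a user-supplied constant measured once from a
scaling slide.

## Segmentation

Otsu's threshold is computed from a 256-bin histogram with exact per-bin
value sums, so the maximized between-class variance equals the brute-force
criterion at every candidate cut. Bright-field leaves are darker than the
agar background, so the lower class is the default foreground (`polarity`).
Opening with a disc larger than the broadest trichome (default radius 25 px,
tunable) removes trichomes that protrude over the leaf outline; holes are
filled afterwards because trichome stalks crossing the leaf edge otherwise
puncture the mask. For leaves that resist automatic segmentation,
`manual_leaf_polygon()` rasterizes the convex hull of a hand-drawn outline
(a pixel belongs if its center is inside or on the boundary).

## Elastic-map surface fitting

The in-mask height-map pixels form a noisy 3D point cloud S. The surface
model is an elastic map: a rectangular grid of nodes with three energies —
the mean weighted squared distance of points to their host (nearest) nodes,
a stretching term λ·Σ(squared edge lengths), and a bending term µ·Σ(squared
second differences along grid rows and columns). EM alternates host
assignment with an exact sparse solve of the quadratic in the node heights;
the total energy is non-increasing and iteration stops at relative change
`tol = 1e-5` (or `max_iter = 100`).

Design choices that were genuinely open:

* **Node lattice fixed in (x, y), heights free.** The fitted map is used
  downstream as a single-valued height field z′ = f(x, y) — bilinear
  evaluation, per-cell triangulation, projected/3D distortion all assume it.
  Allowing lateral node motion can fold the grid in (x, y) and make f
  multivalued, so the M-step solves for heights only. The cost is a known
  artifact of host-node quantization: for clouds that sample an inclined
  surface uniformly in area, *boundary* nodes see one-sided host regions and
  pick up an offset of order slope × node spacing. Interior accuracy is
  unaffected at practical slopes, and surfaces sampled at the lattice are
  reproduced to machine precision.
* **Coordinate normalization.** The fit internally rescales all coordinates
  by the largest lateral extent, so λ and µ act on a unit-size problem and do
  not need re-tuning per leaf size.
* **Defaults λ = 1e-4, µ = 1e-3.** Chosen on synthetic fixtures (a noisy
  plane and a noisy Gaussian bump, σ = 3 µm, 30×30 grid): both are recovered
  with RMS ≈ 0.7 µm, well below the noise, while stronger smoothing
  (e.g. λ = 0.01, µ = 0.1) visibly flattens the bump (RMS 4.4 µm > σ). Any
  positive µ or λ also keeps the linear system well-posed when some nodes
  host no points; with λ = µ = 0 and empty nodes the fit aborts and names
  them.
* **Initialization** is the least-squares plane through the cloud, evaluated
  at the lattice — deterministic and rotation-robust.
* **Triangulation** splits every grid cell along the same (lower-left to
  upper-right) diagonal; the area difference between the two possible
  diagonals is a second-order mesh artifact, and a fixed choice keeps output
  bytes reproducible.

## Geodesic distances

Geodesics are first-order eikonal solutions on the triangulated surface:
fast marching with the classical two-vertex update, with two accuracy
safeguards. Obtuse angles (unavoidable once grid cells are lifted onto a
steep surface) are handled by unfolding adjacent triangles in the plane
until a vertex splits the obtuse wedge, creating virtual update stencils;
after the marching pass, Gauss–Seidel sweeps over all stencils repair any
residual causality violations. Second, the solver seeds all vertices within
8 mean-edge-lengths of the source with their straight-line distance: this
removes the O(h) source-singularity error of first-order schemes at a
curvature cost of O((8h)³/ρ²) (ρ = local curvature radius), which is
negligible whenever ρ spans more than a few cells. Measured accuracy: ≤ 0.4%
of the planar distance on a flat 100×100 mesh and ≤ 0.9% of the great-circle
arc on a 200×200 hemisphere cap. Arbitrary surface points (not only
vertices) are handled barycentrically at both ends; distances between points
in one triangle fall back to the in-triangle straight line, so d(a, a) = 0.

## Voronoi tessellations

The planar tessellation is computed per generator by intersecting bisector
half-planes (quadratic in the number of trichomes, which is small). A cell
that reaches a far bounding box is unbounded — exactly the convex-hull
generators — and is flagged infinite and excluded from area statistics, as
border effects would otherwise dominate; finite cells are clipped to the
leaf polygon. On the surface, no exact geodesic Voronoi algorithm is
practical, so each mesh triangle is assigned via its centroid to the
generator minimizing 3D Euclidean distance; a cell's area is its triangles'
summed 3D area, and cells touching the mesh boundary play the role of the
planar infinite cells. The centroid granularity error shrinks with mesh
resolution (≈ 1–2% of cell area at the default grids).

Note the two finiteness notions genuinely differ: a planar cell can be
bounded yet still touch the leaf edge, in which case the 3D rule flags it
marginal while the 2D rule keeps it. Tests compare areas where both rules
keep the cell.

## Frames, meta leaf and genotype comparison

Each leaf carries a frame: the origin in the middle of the petiole at the
lamina base and the longitudinal axis to a tip point; both are user-supplied
(an optional centroid-based tip suggestion is available via
`suggest_frame()`). Normalization translates, rotates and scales so the tip
is at (0, 1); every meta-leaf statistic is invariant under similarity
transforms of a leaf together with its frame. Base distances are emitted
both normalized and in µm, since either scale can be of interest.

Only leaves with one to six mature trichomes enter the analysis — leaves are
staged by their mature-trichome count, so that count is a selection variable,
and `compare_genotypes()` consequently reports class-4 (mature) rows but
does not test them. Tests are two-sided Wilcoxon rank-sum: exact when
n_a + n_b ≤ 20 with no ties, otherwise the normal approximation with tie and
continuity corrections. Densities and morphometrics (3D area, length, leaf
index) are compared across leaves; Voronoi areas and geodesic
nearest-neighbor distances across trichomes pooled within genotype. P-values
are reported raw; a Benjamini–Hochberg column is included for reference but
does not drive the significance flags.

# The synthetic world

The generator exists so that every stage can be tested against ground truth,
and its defaults state the physical scenario the package targets: a young
leaf a few hundred µm long imaged at 2 µm/px with a 10× objective, 60
z-slices at 3.4 µm/slice (a 170 µm cover-slide reference spanning 50
slices), leaf darker (mean 0.35) than the agar background (0.75) in bright
field. Texture is band-limited uniform noise (correlation length 2 px,
peak-to-peak contrast 0.5); defocus is a Gaussian blur whose σ grows
linearly away from the surface, σ(z) = σ0 + k·|z − h| with σ0 = 0.5 px and
k = 0.3 px per slice — the simplest monotone model under which
argmax-sharpness recovers the surface. Surfaces come from named families
(plane, tilted plane, Gaussian bump, cylinder section, hemisphere cap).
Trichome patterns are hard-core (minimum-distance) point processes inside
the mask with classes arranged in longitudinal zones — mature trichomes
distal, initiation sites basal, with adjustable overlap — mirroring the
developmental zonation of young leaves.

What the generator does **not** emulate: optical PSF structure (defocus is
an isotropic Gaussian, not a diffraction pattern), trichome pixels (the
stalks and branches are not rendered; annotations are coordinates), uneven
illumination, stage drift between slices, and specular highlights. A green
pipeline test therefore establishes that the algorithms are implemented
correctly under the stated image-formation model, not that any particular
microscope will reach the same accuracy.

# Numerical conventions

* Pixel coordinates are 0-based, (x = column, y = row), pixel-centered;
  z index 0 is the first acquired slice. Intensities are min–max normalized
  per stack — sharpness comparisons are within-stack, so absolute scale
  carries no information.
* Argmax ties over z go to the lowest slice; Otsu criterion ties go to the
  lowest threshold.
* Geodesic solver tolerances: repair sweeps stop at relative change 1e-12 or
  30 sweeps; source seeding radius 8 mean edge lengths.
* Degenerate inputs fail loudly with typed messages: constant images (no
  Otsu threshold), stacks with fewer than 2 slices, equal calibration
  indices, empty masks, λ = µ = 0 with empty host nodes (named), out-of-domain
  surface queries, disconnected mesh targets, collinear Voronoi generators,
  infeasible hard-core spacing (capped rejection sampling).

# Known limitations

* The elastic map is a height field: leaves folded back over themselves
  (multivalued z) are out of scope, as is any topology other than a
  rectangular patch.
* Boundary nodes of the fitted map are biased by O(slope × node spacing) on
  steeply inclined regions (see above); statistics that integrate over the
  mask interior are insensitive to this, but per-node heights at the mask
  edge should not be over-interpreted.
* Sub-slice height refinement is not attempted; height quantization is one
  slice, and the elastic map is what smooths it.
* The 3D Voronoi tessellation uses 3D Euclidean (not geodesic) proximity,
  with triangle-centroid granularity.
* Supported image formats are uncompressed grayscale 8/16-bit TIFF (single-
  or multi-page); PNG and compressed TIFF are not read or written.
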