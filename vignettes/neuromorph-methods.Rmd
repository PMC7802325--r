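---
title: "Methods: multi-scale morphometry of embryonic brains and apical lattices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-scale morphometry of embryonic brains and apical lattices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromorph)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical choices made where the design
was open, and what the synthetic-data tests do and do not demonstrate
about real imaging data.

## The measurement problem

Embryonic mouse brains imaged by light-sheet microscopy are segmented
into closed iso-surfaces (outer cerebral cortex; combined lateral
ventricles) and, at much higher magnification, the apical surface of the
cortical neuroepithelium is segmented into a polygonal lattice of cell
apices. The pipeline quantifies both scales with a small set of
descriptive statistics suitable for very small cohorts (n = 2–5 animals
per genotype): no hypothesis tests run by default, and `compare_groups()`
only adds an exploratory Welch t-test behind a flag.

## Organ-scale model

**Volume and area.** A surface is carried as a `tri_mesh` (vertices in
mm, triangular faces with consistent outward winding). Volume is the
divergence-theorem sum of signed tetrahedra against the origin — exact
for any closed triangulation and translation-invariant; the sign is
validated (an inward-wound mesh raises an error rather than being
silently negated). Area is the triangle-area sum. Closedness (every edge
shared by exactly two consistently wound faces) is a precondition for
volume and is checked on every call.

**Sphericity.** Per ventricle lobe, \(S = \pi^{1/3}(6V)^{2/3}/A\). By the
isoperimetric inequality \(S \le 1\) with equality only for the sphere,
so the pipeline asserts \(S \le 1 + 10^{-6}\) on every mesh it measures.
A discretized sphere sits slightly below 1 (≈ 0.9995 at icosphere
subdivision level 4) because the inscribed polyhedron loses relatively
more volume than area.

**Cortical thickness.** The cortex is treated as a hollow shell:
\(h = 2V_{\mathrm{cortex}}/(A_{\mathrm{outer}} + A_{\mathrm{inner}})\),
with \(V_{\mathrm{cortex}}\) the outer-surface volume minus total
ventricular volume, \(A_{\mathrm{outer}}\) the outer cortical area and
\(A_{\mathrm{inner}}\) the (uncut) ventricular surface area. For a
cylindrical wall the formula is the exact wall width; for strongly
curved thick shells it is biased low relative to the radial thickness
(for concentric spheres with radii \(r < R\) it returns
\((R^3 - r^3)\,2/(3(R^2 + r^2))\), which approaches \(R - r\) only in the
thin-shell limit). The formula is applied exactly as stated, and the bias
is documented rather than corrected, so that values remain comparable
with shell-model measurements in the imaging literature.

**Midline separation.** The two lateral-ventricle lobes are separated by
`split_by_plane()`, the computational stand-in for cutting the
iso-surface at the septum pellucidum. Crossing triangles are subdivided,
the cut cross-section is chained into closed loops and each loop is
triangulated by ear clipping, so both halves are again closed meshes and
volume is conserved exactly (the tested bound is 0.1%, observed ~1e-12
relative). Vertices falling numerically on the plane (within 1e-9 of the
coordinate scale) are classified to the positive side, which keeps every
cut transversal; nested (annular) cross-sections are not supported and
raise an error. Per-lobe area includes the flat septal cap — the same
convention a segmentation tool produces when an iso-surface is split and
re-closed.

**Lobe-wise thickness** (off by default) applies the shell formula to
the plane-split half shells, caps included. The lobe-wise partition of
the areas is not uniquely defined by the shell model; this implementation
is flagged as an interpretation in the function documentation.

## Cell-scale model

**Lattice and border exclusion.** A `cell_lattice` holds simple 2D
polygons (µm), a symmetric adjacency relation, and border flags. All
statistics are computed over interior cells only, mirroring segmentation
practice where cells clipped by the field of view are discarded. Border
cells still contribute their own neighbour counts to the Aboav averages
of interior cells; their counts are lattice-truncated, which is the same
truncation real border-excluded segmentations carry.

**Topology.** For a trivalent tessellation Euler's relation forces a
mean neighbour number of 6; on periodic lattices the package recovers
this exactly (the suite asserts |mean − 6| < 0.02 on 2000 cells), while
bounded lattices sit slightly below 6 among interior cells because
border neighbours absorb part of the defect balance.

**Lewis' law** relates a cell's neighbour class n to its class-mean
relative area, \(\bar A_n/\bar A = (n-2)/4\). **Aboav-Weaire's law**
relates n to the mean neighbour number m(n) of the surrounding cells.
Two algebraic forms of the latter circulate; this package defaults to
the standard form \(m(n) = 5 + 8/n\), i.e. \(n\,m(n) = 5n + 8\) linear
in n with m(n) increasing toward ~6, which is the behaviour observed in
epithelia and in our own Voronoi mosaics (fitted n·m(n) slope ≈ 5.1–5.4,
intercept 5.5–7). A decreasing variant \(m(n) = 5 - n/8\) is kept
available as `form = "literal"` so both conventions can be compared
explicitly; it is never the default because it contradicts the measured
m(n) of every lattice this package generates.

`empirical_law_tables()` fits both laws by least squares weighted by
class counts, using only classes with ≥ 5 cells and n ≥ 3 (classes below
the triangle arise only as segmentation artifacts). On a lattice
*constructed* to satisfy Lewis' law exactly (cell polygons rescaled so
each area is the class value; periodic adjacency untouched, so the mean
neighbour number is combinatorially 6) the fit returns slope 0.25 and
intercept −0.5 to machine precision — this separates fit correctness
from lattice physics. Empirically, Poisson-Voronoi mosaics give a Lewis
slope ≈ 0.22, one Lloyd step ≈ 0.16, and strong relaxation flattens the
area–class relation toward 0.1 as Lloyd's algorithm equalizes areas;
the property test therefore pins the slope of a lightly relaxed
(1-step) 2000-cell mosaic inside [0.15, 0.30].

**Aspect ratio.** Each cell is summarized by the ellipse with the same
area-weighted second central moments as its polygon interior (closed
form by Green's theorem); the aspect ratio is
\(\sqrt{\lambda_{\max}/\lambda_{\min}}\). This is a deterministic
reading of "fit an ellipse and extract the axes": it is exact for true
ellipses (an inscribed 64-gon of a 3:1 ellipse returns 3.0 to machine
precision, as the polygon is an affine image of a regular 64-gon), and
invariant to rotation, translation and uniform scaling (tested to
1e-9 over 100 random rotations). Cells given as 3D loops are first
projected onto their own best-fit plane (principal components), the
planar simplification of curvature-aware 2.5D measurement. Cell areas
are planar throughout; geodesic areas on the curved tissue are out of
scope and the flat approximation is the documented convention.

**Label images.** `adjacency_from_labels()` reconstructs the lattice
from an integer raster: two cells are adjacent when they share at least
2 four-connected pixel-edge contacts (one contact is allowed to be a
corner artifact; requiring two stabilizes trivalence at finite
resolution), frame-touching labels are border-flagged, outlines are
traced from label boundaries (EBImage contour tracing), and areas are
pixel counts times the pixel area. The only systematic failure mode is
physical, not algorithmic: a tessellation edge shorter than about two
pixels cannot produce two contacts, so sub-resolution junction slivers
lose their adjacency. At 0.1 µm/px this affects several percent of the
cells of a Poisson-Voronoi mosaic (whose edge-length density is finite
at zero) but under 1% of a strongly ordered mosaic; the
oracle-equivalence test therefore uses a near-centroidal lattice
(100 Lloyd steps, mean cell area 40 µm², 400 cells), which is also the
regime that resembles a real epithelium more than an unrelaxed mosaic
does.

## Synthetic-data generator

The generator is the study's source of ground truth, not a tissue
mechanics model: group differences are produced by shifting the target
means, not by simulating Chd8 biology.

**Solids.** Spheres/ellipsoids are subdivided icosahedra (level 4 ≈
5120 faces, volume within 0.25% of the closed form); "blobs" add a
smooth deterministic random radial field (sum of six low-frequency plane
waves; amplitude 0 reproduces the sphere bit-for-bit). Hollow cylinders
are closed shells whose side walls realize the thickness identity
exactly (up to the polygonal factor cos(π/n)).

**Brain phantom.** Per sample: (1) the outer cortical surface is a blob
(relative amplitude 0.08) rescaled so its *mesh* volume equals the drawn
brain-volume target exactly; (2) the ventricular surface is an
axisymmetric dumbbell — the union of two prolate spheroids with centres
at ±0.62 a, meshed as a surface of revolution with no vertex ring on the
midline so the split is always transversal; lobe elongation is tuned by
bisection (tolerance 1e-5) against the *mesh-measured* sphericity of the
half lobe, making the end-to-end recovery error ~1e-8 rather than the
~1e-3 a smooth-formula calibration would leave; near-spherical targets
(above the sphericity of a maximally overlapped spherical lobe, ≈ 0.97)
are instead reached by reducing the lobe overlap, and targets > 1 are
rejected as unreachable; (3) the dumbbell is rescaled so the shell
formula evaluates to the drawn thickness target exactly (cubic solved by
`uniroot` on the mesh-measured quantities), which implicitly sets the
ventricular volume — the study configuration specifies sphericity,
thickness, volume and distance, so ventricular volume is the free
parameter that absorbs the constraint; (4) pupils are placed exactly at
the drawn intraocular distance. The phantom is a *metric* phantom: its
surfaces realize the target quantities but are not anatomically nested
renderings of a brain.

**Study.** `study_config()` defaults encode the cohort the pipeline is
designed around: WT n = 2 with sphericity 0.70 ± 0.01, intraocular
distance 1.75 ± 0.002 mm, thickness 0.08 ± 0.02 mm, brain volume
3.28 ± 0.18 mm³ (mean and sample SD of the two reported animals — those
metrics are published as two individual values, so the config flags them
as range-derived); HET n = 5 with 0.67 ± 0.03, 1.85 ± 0.10 mm,
0.10 ± 0.03 mm, 3.60 ± 0.56 mm³. All ± values are taken as sample SDs
(n − 1): an SD of 0.002 on two values is consistent with two nearly
identical measurements, whereas reading them as SEMs would be
ill-defined at n = 2. Ventricle-level metrics are pooled per lobe (2
brains → n = 4 ventricles); brain-level metrics are per animal.
Per-sample targets are independent truncated-normal draws (sphericity
capped at 0.995, the reachable mesh range; lengths and volumes positive;
truncation by resampling) — with the default means the truncation is
never active in practice. Lattices default to the segmented cell counts
of the two reference samples (1031 and 3854 cells) with no Lloyd
relaxation, because an unrelaxed Voronoi mosaic's hexagon fraction
(~30%) matches the observed 29–31% directly. Everything is deterministic
under the master seed, including the written PLY/CSV/TIFF files
(byte-identical regeneration is tested).

**What passing tests do not show.** The generator emulates the
*quantities* the pipeline measures, not the imaging physics: no
fluorescence, clearing distortion, contouring error, or watershed
over-/under-segmentation. Parameter recovery on phantoms demonstrates
that the measurement chain is unbiased at the stated tolerances on
meshes and rasters of this quality; it cannot certify accuracy on real
iso-surfaces, whose interpolated-contour provenance has no published
algorithmic definition (we adopt exact mesh formulas and accept a small
systematic offset against interactive tools).

## Numerical choices

- Units are fixed: mm/mm²/mm³ at organ scale, µm/µm² at cell scale.
- Mesh tolerances are stated per test relative to refinement (0.5% for
  level-4 spheres), never as one global epsilon.
- Ear clipping operates on each cut loop in its own planar basis with a
  fallback that removes the flattest corner if no strict ear exists
  (near-collinear loops from fine meshes).
- The Voronoi engine clips each generator's starting square by bisectors
  of candidates in increasing-distance order and stops once the next
  candidate is farther than twice the current maximal vertex distance —
  a rigorous sufficiency bound, so cells are exact, not approximate;
  periodic mode replicates only near-edge generators into image tiles.
  Lloyd steps move generators to exact polygon centroids.
- Rasterization snaps the pixel grid to tile the square domain exactly
  (realized pixel size within a fraction of a percent of the request) so
  no background frame is introduced and border flags stay exact.
- Degenerate inputs fail loudly: open meshes for volume, inward winding,
  planes that miss the mesh, empty label images, all-border lattices,
  sub-triangle polygon classes, non-positive sphericity inputs.

## Problem sizes used by the test suite

The suite runs at desk scale: icosphere level 4 (5120 faces) for
closed-form checks; 2000-cell periodic mosaics for topology and law
properties; 400-cell strongly relaxed mosaics at 0.1 µm/px for
oracle-equivalence of the label-image path; and 20 replicate studies of
50 + 50 animals (phantoms at reduced refinement, lattices off) for group
parameter recovery, which bounds every recovered group mean within 3
standard errors of its configured value.

## Known limitations

- The thickness formula's thin-shell bias on curved anatomy (above).
- Annular plane cuts (tori, shell cross-sections) are unsupported.
- Sub-resolution lattice edges cannot be recovered from rasters at any
  contact threshold; resolution, not code, is the limit.
- The generator's two lobes are mirror-symmetric; left/right asymmetry
  analyses would need an asymmetric phantom.
- Sphericity targets above ≈ 0.995 are unreachable for a two-lobed
  surface with a neck, and the truncation of sphericity draws reflects
  that.
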