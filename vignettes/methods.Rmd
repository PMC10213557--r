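---
title: "Quantitative 3D morphometrics of ovule primordia: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative 3D morphometrics of ovule primordia: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(primordium3d)
```

# The problem

During the somatic-to-reproductive transition in flowering plants, a single
subepidermal cell at the apex of each ovule primordium — the megaspore
mother cell (MMC) — is singled out from a pool of morphologically similar
candidate cells, enlarges, elongates, and enters meiosis. In maize this
happens inside a dome of a few hundred cells, 30–60 µm across. Quantifying
how the MMC and its neighbors differ in size, shape, wall geometry and
division behavior requires segmented, labeled 3D image volumes and a
reproducible analysis chain on top of them.

`primordium3d` provides that chain: two-level cell-type annotation (layers
L1–L4 and radial contact classes centered on the central L2 cell), per-cell
and per-organ shape descriptors, geometric inference of recent cell
divisions with shortest-wall division-plane prediction, developmental
staging by optimal one-dimensional clustering, and the accompanying
non-parametric statistics. A synthetic ovule generator produces labeled
dome tissues with known ground truth so every step can be validated by
parameter recovery.

# Data model and conventions

A `labeled_volume` is a 3D integer grid (0 = background, one positive label
per cell) with physical voxel sizes `(dz, dy, dx)` in µm; arrays are
indexed `(z, y, x)` with the physical center of 1-based voxel `(k, j, i)`
at `((i − 0.5)dx, (j − 0.5)dy, (k − 0.5)dz)`. All lengths are µm, areas
µm², volumes µm³. Anisotropic voxels are supported throughout; typical
acquisitions use 0.3 µm cubic voxels, while the synthetic tests use coarser
1 µm grids.

Ovule crops terminate in tissue at their base, so the minimum-z grid face
(`base_plane`) is *not* treated as free surface: cells touching only that
face do not count as epidermal, and the exterior-distance field that
underlies layer geometry is computed with the base face closed.

# Annotation

**Adjacency.** Two cells are adjacent when they share at least one voxel
face (6-connectivity; diagonal contacts are treated as segmentation
artifacts). Edge interface areas are face counts times face area; edges
below `min_contact_area_um2` (default 1 µm²) are dropped as speckle.

**Layers.** L1 is the set of cells with an exterior contact; each next
layer is the set of still-unassigned cells adjacent to the previous one;
everything at graph distance above 3 is L4.

**The central L2 cell.** The apical (dome) axis is estimated from the
principal axes of the L1 exterior-contact cloud, keeping the axis best
aligned with the grid z-axis and falling back to z when the cloud is
near-isotropic (eigenvalue ratio below 1.2). Among L2 cells, the central
cell is the one with the greatest *apical reach* — the 95th percentile of
its voxel projections on the apical axis. We use reach rather than the
centroid deliberately: a strongly elongated MMC carries most of its volume
basally, so its centroid sits below those of apex-flank neighbors even
though its apex touches the dome tip; the reach criterion is stable across
that whole shape range. Ties within 0.5 µm go to the candidate closest to
the axis line.

**The stack cell.** Among L3 neighbors of the central cell, the stack cell
is the one best aligned with the central cell's major ellipsoid axis on the
basal side. When the central cell is not clearly prolate along the dome
axis (major axis more than 45° off-axis — the situation right after a
periclinal division, when the apical daughter is a flat cap), the dome axis
itself is the reference. Real datasets resolved multiple-candidate cases
visually; this rule is the package's deterministic substitute.

# Cell morphometrics

Volumes are voxel counts times voxel volume, so they are conserved exactly
over any tessellation. Surface areas come from triangulated iso-surfaces:
the binary cell mask is Gaussian-smoothed (σ = 0.6 voxels) and contoured at
0.5 by marching tetrahedra with linear interpolation, then Taubin-smoothed
(10 iterations, λ = 0.5, µ = −0.53). Raw voxel-face counting is never used
for areas — it overestimates oblique surfaces by up to ~50% and would
corrupt sphericity. The smoothing constants were fixed against analytic
solids: a 20-voxel-radius digital ball reproduces 4πr² within ~2% and a
20³ cube its 2400 µm² within ~5% (the residual is corner rounding).

The fitting ellipsoid comes from the second central moments of the voxel
centers (plus the within-voxel variance term `side²/12`, which makes the
moments of a voxelized solid match the continuous solid); semi-axes are
`√(5λᵢ)`, exact for a uniform solid ellipsoid. Reported shape descriptors:

* normalized axis lengths `A, B, C` divided by `A + B + C` (scale-free, so
  the semi-axis convention is immaterial);
* two-axis anisotropy `C / (A + C)`, in [0.5, 1);
* sphericity `ψ = π^{1/3}(6V)^{2/3}/A_surf`, 1 for a ball;
* prolate ellipticity `(c − b)/c` and oblate ellipticity `(b − a)/b` from
  semi-axes `a ≤ b ≤ c`. Commercial packages report "prolate/oblate
  ellipticity" without published formulas; these definitions are bounded in
  [0, 1), zero on the ball, monotone in elongation/flattening, and preserve
  the qualitative contrasts of interest, but are not numerically identical
  to any proprietary implementation.

# Wall geometry and division inference

**Interface meshes.** The wall between two cells is the subset of the
smaller label's surface mesh whose triangles face the other label (the
label grid is sampled a fraction of a voxel on each side of every triangle
centroid). Computing the patch from the canonical cell of the pair makes
the area exactly symmetric. A principal-axis plane fit provides the wall
normal and an RMS planarity residual.

**Junction wall angle.** For a candidate daughter pair, every third region
X adjacent to both cells (side patches of at least 4 µm² each) contributes
one measurement: the centroids of the upper–X and lower–X wall patches and
the junction point where the two patches meet define an angle at the
junction; walls in perfect continuity give ~180°. Two details matter. The
angle is measured in the cross-sectional plane perpendicular to the
junction line, so lateral (in-plane) offsets of irregular patch centroids
do not masquerade as lost continuity. And the mean over all qualifying
sides is reported — a manual protocol would pick one side by eye; averaging
removes that operator choice. A pair is called a *recent division* when the
mean angle reaches `continuity_threshold_deg` (default 160°; every call
records its angle, so re-thresholding is free).

**Division plane prediction.** The geometric rule for symmetric divisions
is that the new wall is the shortest wall through the cell center. The
predictor scans ~500 quasi-uniform directions (Fibonacci half-sphere) plus
local refinements with shrinking angular caps, measuring each candidate
section by a voxel-scale slab through the mask centroid with a triangular
weighting window (width 2 voxels). The window matters: plain one-voxel box
counting carries ±10% direction-dependent quantization noise, enough to
bias any argmin; the windowed estimator is exact on axis-aligned solids and
agrees with analytic ellipsoid sections to well under 1%. The plane is
constrained through the centroid exactly — no offset search. The
observed–predicted (o-p) angle is `arccos|n₁·n₂|`, folded to [0°, 90°].

**Orientation.** A wall is periclinal when its normal is within 30° of the
local radial direction (the outward normal of the nearest exterior
surface, computed as the negative gradient of the exterior-distance field),
anticlinal beyond 60°, oblique between. The same radial convention is used
by the generator, so planted and inferred orientations are commensurable.

**Ovule types.** An ovule is Type 2 when its central L2–L3 pair shows wall
continuity at the threshold, Type 1 otherwise; a missing stack cell gives a
flagged Type 1.

# Staging and statistics

Stages are defined by the volume of the central L2 cell. Clustering is
globally optimal 1D k-means by dynamic programming — deterministic, no
seeding — computed on log volumes by default: growth across stages is
multiplicative (stage means double), so the log scale keeps per-stage
spread comparable and stops the largest stage from dominating the WSS. The
elbow suggestion is the k maximizing the locally normalized curvature
`(WSS(k−1) − 2WSS(k) + WSS(k+1))/WSS(k)`; a maximum below 2 is flagged low
confidence. The suggestion is advisory — the pipeline default is k = 4,
overridable. Floret meristems (stage 0) are excluded from fitting and kept
as stage 0 in the output.

Group comparisons use the Mann–Whitney U test (exact when `n ≤ 20` and
tie-free; seeded Monte Carlo permutation for small tied samples; normal
approximation with tie and continuity corrections otherwise), Fisher's
exact test for divided/undivided counts, and Pearson's χ² on three classes
for anisotropy distributions, with class boundaries at the pooled tertiles
(the three-class boundaries are not standardized anywhere; tertiles are
this package's deterministic choice). Significance codes follow the
standard ladder `* < 0.05, ** < 0.01, *** < 0.001, **** < 0.0001`;
published figure legends are not always internally consistent about the
upper rungs, so the standard ladder is adopted throughout. No
multiple-testing correction is applied across the summary grid; p-values
are reported raw and marked as such.

# Organ shape

The ovule bounding box is the principal-axis-oriented box of the fused
foreground cloud (an axis-aligned box is available behind a flag); lengths
are sorted `A ≤ B ≤ C` and the aspect ratio is `A/(A + B + C)` — the
normalized height, at most 1/3, since A is the dome height and B, C the
base diameters. Dome curvature is computed per vertex of the fused-L1
iso-surface by a local *tangent-sphere* fit over a 40 µm neighborhood,
reduced to 30 µm for meshes with bounding-sphere diameter below 80 µm (the
published protocol reduces the radius for "small" ovules without a numeric
cutoff; 80 µm is this package's). In the outward-normal frame at the
vertex, the sphere through the vertex tangent to its tangent plane
satisfies `x² + y² + z² = 2Rz`, giving the least-squares curvature
`1/R = 2Σz²/Σ((x²+y²+z²)z)`. A quadric fit was tried first and rejected:
the prescribed neighborhoods are large relative to organ curvature radii
(a 30 µm ball on a 25 µm sphere is a 74° cap) and a quadric fitted over
such a cap overestimates curvature by ~50%, whereas the tangent sphere is
exact on spheres at any cap size. Flat patches (height deviations below
2% of the neighborhood scale) report 0; base-cap vertices are masked and
excluded from every fit; neighborhoods are drawn from a spread vertex pool
and capped at 80 points — a one-parameter fit does not need thousands.
Cell–organ shape coupling is summarized by
the Spearman rank correlation between the central cell's normalized major
axis and the ovule aspect ratio, with a permutation p-value (exact
enumeration up to n = 7, otherwise ≥ 10,000 seeded draws); rank correlation
is robust to the stage-clustered structure of such cohorts.

# The synthetic ovule generator

The generator is first-class, tested code. It emulates the statistical
structure of an imaged cohort, not its optics: no wall-signal synthesis, no
microscopy noise, no segmentation errors.

**Tessellation.** A superellipsoid dome
`(x/Rx)² + (y/Ry)² + (z/H)^n ≤ 1, z ≥ 0` is voxelized; seeds are placed on
concentric offset shells (well-spread surface points pushed inward to each
layer band's midpoint depth; interior k-means seeds for L4) and every
foreground voxel is assigned to its nearest seed under an additively
weighted metric — a power-diagram-like rule that guarantees a full
partition. The epidermis is modeled as a clean sheet: L1-band voxels are
contested among L1 seeds only (biologically, L1 maintains itself by
anticlinal divisions and never dips below its band).

**The central cell.** Exactly one L2 seed sits on the dome axis. Its
weight is tuned by bisection so the cell volume hits the target within
15%. Its shape is controlled by two knobs: an axial metric ratio (< 1
cheapens the axial direction, elongating the cell) and a hard lateral
radius derived from the target volume and a per-stage slenderness ratio
`h/2r`. The cell is hypodermal by construction — it may not enter the L1
band.

**Divisions.** `plant_division()` splits a cell at extent fraction `f`.
Periclinal splits follow the depth iso-surface (periclinal walls are
parallel to the organ surface, which in a curved dome is not a flat
plane — a plane would wrap the basal daughter onto the dome flank and give
it spurious epidermal contacts); anticlinal and oblique splits are planar.
With `jitter = 0` the daughters' free walls remain exactly coplanar with
the mother's. With `jitter > 0`, each daughter's wall with each flanking
neighbor is tilted about its mid-line by an independent random amount of
scale `jitter` (µm), with coordinated opposite senses for the two
daughters — the deformation signature independent daughter growth leaves on
walls, and approximately volume-neutral. The junction angle responds
monotonically: ~179° at 0 µm, ~170° at 3 µm, ~145° at 5 µm on ~1 µm grids.

**Cohorts and types.** `generate_cohort()` draws central-cell volumes
log-normally (10% scatter, winsorized at 1.5 SD) around stage means of
500, 1000, 2000, 4000 µm³ for stages 1–4, with dome height, aspect, apex
squareness and central-cell slenderness following the stage (the
developmental narrative: domes grow taller and more pointed, the MMC more
columnar). An organ is Type 2 with the stage's planted probability (0.7,
0.42, 0, 0): its archesporial cell is split periclinally with continuous
walls, at a daughter volume ratio drawn from a symmetric (mean 1.0,
SD 0.05) or asymmetric (mean 2.3, SD 0.1) class, 60:40. Otherwise the
organ is Type 1: the stack cell is generated as a separate near-axis cell
with ordinary walls. This is a deliberate modeling decision: an *old*
division's walls have been fully rearranged by growth, and ordinary
power-diagram walls reproduce the junction-angle statistics of undivided
neighbor pairs (~105–155°), cleanly below the 160° threshold, whereas
jittered planted divisions straddle it. A small lateral jog (1.5–3 µm)
keeps the stack's side walls from aligning with the central cell's by
construction. Two recent periclinal neighbor divisions per organ provide
detection positives.

**What passing recovery tests does and does not show.** The generator's
cells are convex-ish power cells with sharp walls on a clean grid; real
segmentations add wall-thickness effects, curation errors, non-convex
cells and imaging anisotropy. Recovery of planted layers, central cells,
types, stages and orientations therefore validates the pipeline's logic
and geometry, not its robustness to segmentation failure modes — those must
be assessed on real labeled volumes.

# Problem sizes and determinism

The validation suites use 1 µm voxels: single domes of roughly 45–60 voxels
across (30–60 µm organs) and a 40-organ cohort (ten per stage) for
parameter recovery; geometry oracles run on analytic solids of 10–40 voxel
scale, and brute-force direction oracles use a 5,000-direction grid
(10× the search density). One integer seed drives every stochastic draw;
identical seeds give bit-identical volumes, and the pipeline writes its
resolved configuration, input hashes and seed into a run manifest so any
run can be reproduced exactly.

# Known limitations

* Ellipticity and bounding-box conventions are documented substitutes for
  proprietary descriptor implementations; normalized quantities agree, raw
  values need not.
* The junction-angle protocol automates a manual 3-point measurement; the
  all-sides mean is this package's definition of the per-pair angle.
* The Type 1/Type 2 threshold (160°) is a configuration knob, not an
  empirical constant; published classifications were visual.
* Periclinal "oblique" calls depend on the 30°/60° bands, which bound a
  deliberately explicit oblique class.
* The pipeline consumes already-labeled volumes; it does not segment, and
  nothing here corrects segmentation errors.
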