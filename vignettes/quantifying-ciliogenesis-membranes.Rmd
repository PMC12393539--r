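---
title: "Quantifying ciliogenesis membrane intermediates in volume EM"
author: "ciliovem authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ciliogenesis membrane intermediates in volume EM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliovem)
```

## The measurement problem

During primary ciliogenesis, membranes dock to the distal appendages (DAs)
of the mother centriole (MC) and mature through a series of intermediates:
small distal-appendage vesicles (DAVs), a C-shaped tubulovesicular membrane
("C"-ciliary vesicle, CCV), a closed toroidal membrane (TCV), the ciliary
vesicle (CV) capping the distal end, and finally the ciliary membrane
proper. Isotropic FIB-SEM volumes (~9 nm voxels) resolve these structures
in 3D, but turning a segmentation into numbers — how far is a membrane from
the nearest DA tip, how much of the circumference does it cover, how large
is it — requires an explicit geometric frame and reproducible measurement
rules. `ciliovem` implements that pipeline:

1. **Frame fit** — the MC axis, its distal origin, and a theta reference.
2. **DA tips** — one tip point per appendage, the docking reference.
3. **Membrane components** — 26-connected components of the membrane
   label, filtered by a minimal size and section-persistence rule.
4. **Per-component measurements** — Feret diameter, mesh surface area,
   minimal tip distance, and the C-shape gap angle.
5. **Stage classification** — one stage per MC from a fixed decision
   ladder.
6. **Cohorts** — aggregation over cells and standard group tests.

All distances are Euclidean distances between world-coordinate points in
nanometres; volumes are indexed `[z, y, x]` with the voxel-centre
convention (0-based index times voxel size).

## The core statistics

**Docking.** A membrane is docked when its surface lies 30 nm or less
from a DA distal end. The 30 nm figure is the observed mean membrane-DA
separation (~19 nm) plus a ~10 nm resolution allowance. The distance is an
exact point-to-triangle distance from the tip point to the component's
extracted isosurface, not a voxel-grid distance: the quantities of
interest (tens of nm) span only 2-3 voxels, where distance-transform
quantization would dominate.

**C-shape gap.** In the centriole frame, every mesh vertex of a component
has an azimuth theta. Sorting the azimuths ascending and taking the
largest difference between consecutive values — including the wrap-around
term, so a closed toroid scores a near-zero gap rather than a spurious
360 — gives the C-shape gap. Coverage is `360 - gap`. A CCV is a docked
component with gap strictly below 180 degrees (more than half the
circumference covered); when a gap is available, DA tips whose azimuth
falls strictly inside the empty arc are excluded from docking decisions
and mean-distance summaries, since no membrane can face them.

**Vesicle filter.** A component counts as a vesicle when it spans at
least two consecutive sections and its 3D Feret (maximal pairwise point)
diameter exceeds 30 nm — the lower size limit of cellular vesicles and of
reliable detection at this resolution. Feret is the conservative choice
for irregular tubulovesicular shapes.

**Surface area.** The sum of triangle areas of the component's extracted
isosurface, in nm². Enlargement flags mark areas strictly greater than
`mean + 1 SD` (sample SD) of a reference cohort; strictness avoids
silently flagging boundary ties.

**Stage ladder.** One stage per MC, most advanced docked structure wins:

| Order | Stage | Rule (docked components only) |
|---|---|---|
| 1 | CILIUM | axial extent above the distal end > 500 nm |
| 2 | CV | >= 90% of the distal disk covered in axial projection |
| 3 | TCV | gap <= closure tolerance and all vertices outside MC radius / 2 |
| 4 | CCV | gap < 180 degrees |
| 5 | DAV | any docked component |
| 6 | NAKED | none |

The ladder encodes the editorial convention that an MC with both DAVs and
a CCV is reported at the CCV stage.

## Tunable parameters

All thresholds live in `analysis_config()` and are exposed as CLI flags:

* `dock_threshold_nm = 30` — docking rule (nm).
* `min_vesicle_diameter_nm = 30`, `min_z_slices = 2` — vesicle filter.
* `dav_ccv_gap_deg = 180` — DAV/CCV boundary (degrees).
* `tcv_closure_deg = NULL` — closure tolerance for calling a loop closed;
  the default is the angular footprint of one voxel at the component's
  mean radius (~2.5 degrees at 9 nm and ~210 nm radius). Any fixed value
  must stay well below 10 degrees, since near-closed C-shapes with 10
  degree gaps are real intermediates that must remain CCVs.
* `cilium_axial_extent_nm = 500` — equal to the MC length; a membrane
  extending a full MC length beyond the distal end is a cilium. The
  literature identifies cilia morphologically; this numeric stand-in is
  this package's choice and is config-exposed.
* `cv_occupancy_fraction = 0.9` — CV call. No numeric criterion exists in
  the literature ("covering the distal end"); we project the component's
  voxels above the distal plane (0 < z <= `cilium_axial_extent_nm`) onto
  the distal disk of radius `mc_radius` (cells of 2 voxels) and require
  90% of disk cells covered. A dome covers every column; arcs, tori and
  tubes project to annuli outside the disk and score near zero. An
  alternative reading — sampling the membrane only at 0 < z <= 50 nm —
  cannot work for a dome-shaped CV, whose surface at those heights lies
  at radii far outside the disk.
* `enlargement_sd_multiplier = 1` — enlargement rule.
* `theta_source = "mesh"` — gap azimuths from mesh vertices (the
  segmentation-mesh reading); `"voxels"` uses voxel centres as a
  cross-check mode. Both agree to well under the voxel's angular
  footprint on phantoms.

## Numerical choices

**Isosurfaces.** Meshes are extracted by marching tetrahedra (each grid
cube split into six tetrahedra around its main diagonal) at iso-level 0.5,
with vertices deduplicated per grid edge so meshes are watertight. On raw
binary masks any marching method overestimates area substantially
(staircase surfaces); one pass of a 3x3x3 box mean before extraction
restores sub-voxel surface placement and brings sphere and torus areas to
~1% of their closed forms at 9 nm voxels. `smooth_iters` controls the
number of passes.

**Hole filling.** Membrane segmentations are thin shells; meshing a shell
directly yields two leaflets and roughly double the area. Each component's
interior cavities are therefore filled (6-connected flood from the crop
border) before meshing, so closed shells contribute a single outer
surface, directly comparable to analytic areas and standoffs. Voxels of
*other* labels act as walls during the flood: a membrane whose lumen is
closed off by the MC body (e.g. a ciliary pocket hugging the MC wall)
still fills correctly instead of leaking through the contact.

**Frame fit.** The axis is the dominant principal component of the
mc_body voxel centres, oriented distal by the DA centroid; a principal
variance ratio below 1.2 is rejected as degenerate. The origin sits on
the axis at the distal face: lateral position from the centroid of the
distal-most 10% of voxels, axial position at the robust (99.5 percentile)
maximal projection plus half a voxel. Without a DA label the distal
direction is ambiguous and the fit refuses to guess. The theta = 0
reference (world +x projected off-axis, +y fallback) is arbitrary; every
reported quantity is invariant to it.

**DA tips.** Each DA is a 26-connected component; the tip is taken from
the voxels within one voxel of the component's maximal radial distance —
direction (theta, z) from that band's centroid, radius from the farthest
voxel. A single farthest-voxel pick showed several-degree azimuth jitter
on blunt appendage ends at 9 nm voxels; the band estimate is equally
deterministic and sub-voxel accurate.

**Degenerate inputs.** Points on the axis get theta = 0 by convention.
Components with fewer than 3 azimuth samples have no gap (recorded as
`NA`, treated as gap >= 180 downstream). An empty membrane label is a
valid NAKED observation, not an error. Gap ties resolve to the first
maximal spacing after sorting, making results independent of vertex
ordering.

## The phantom generator

Real FIB-SEM segmentations of these intermediates are not publicly
deposited, so validation uses voxel phantoms with exact analytic ground
truth: an MC cylinder (300 nm diameter, 500 nm length), nine radial DA
pins at a configurable offset below the distal face, and membranes built
from geometric primitives — spheres (DAVs), arc tori with flat ends at
exact limiting angles (CCVs; flat ends keep the built arc span exact,
where rounded ends would bias the measured gap by ~atan(r/R) per end),
closed tori (TCV), a spherical dome dipping below the distal face to
reach the tips (CV), an axial sheath tube (cilium), and plane sheets
(plasma membrane). Closed primitives are rendered as inward shells whose
outer boundary is the analytic surface; ground-truth gap angles, areas
(4&pi;r², 4&pi;²Rr scaled by arc fraction) and tip standoffs are computed in
closed form before voxelization, so voxelization error is what the tests
measure. Label precedence is total (mc_body > da > membrane > pm) and
applied at paint time.

Cohorts draw uniform parameters and Haar-uniform random orientations from
a seeded RNG. The stage-confusion suite samples docking standoffs in
[5, 20] nm — clear of the 30 nm threshold by more than the voxelization
tolerance, exactly as gap spans near the 180 degree boundary are chosen
outside the angular tolerance band; the docking step function itself is
probed by dedicated boundary phantoms at 3 nm voxels (28-31 nm standoffs).

What the phantoms do **not** emulate: imaging noise, milling artifacts,
segmentation errors, membrane thickness variation, EMC tubules connecting
membranes to the plasma membrane, or the empirical distribution of real
vesicle sizes and positions. Passing tests therefore demonstrate that the
geometry and statistics are computed correctly at the stated resolutions,
not that segmentation of real data is reliable.

## Problem sizes

The validation suite uses grids of roughly 100-200 voxels per side
(~1-2 um at 9 nm): eight arc phantoms across the full gap range, 36
randomized phantoms (six per stage) for the confusion matrix, 20 random
poses for frame recovery, boundary docking pairs at 3 nm voxels, and 100
simulated two-group cohorts (n = 10 cells per group, lognormal areas with
CV 0.3) for the power and size of the pooled t-test. These sizes were
chosen so each property is exercised across its full parameter range with
comfortable statistical margins.

## Statistics

Group comparisons follow the conventions of the source analyses: unpaired
two-tailed Student t-test (pooled variance; Welch behind a flag) for two
groups, one-way ANOVA for more, stars at P < 0.05 / 0.01 / 0.001, no
multiple-testing correction by default (optional Holm correction would be
a one-line `p.adjust` on the returned p-values). Docking distances pool
per-DA minima across cells; per-cell means are available because the
pooling convention in published figures is not always explicit.
Dispersion is reported as SEM for docking distances and SD for counts and
areas; SEM/SD for n = 1 is reported absent, never zero.

## Known limitations

* Open-surface structures (domes, sheets, tubes) are meshed with both
  leaflets; their areas are roughly twice the one-sided value. All
  area-bearing comparisons in the pipeline concern closed structures.
* The Feret-diameter shortcut for very large components (directional
  extreme points for > 1500 voxels) is exact only for the extreme pairs
  the 200 sampled directions expose; the residual error is far below a
  voxel.
* The CV occupancy and cilium-extent thresholds are this package's
  numeric stand-ins for morphological judgements; they are config-exposed
  and should be reported alongside any results that depend on them.
* PCA axis fitting assumes an elongated MC; strongly truncated volumes
  (variance ratio < 1.2) are rejected rather than fitted.

## A worked example

```{r example, eval = FALSE}
library(ciliovem)

# a C-shaped membrane phantom with a 93 degree gap, randomly oriented
set.seed(1)
ph <- build_phantom(stage_phantom_spec("CCV", gap_deg = 93,
                                       orientation = random_rotation()))
report <- analyze_cell(ph$volume, cell_id = "demo")
report$stage                 # "CCV"
report$components$gap_deg    # ~93
report$components$min_distance_nm  # ~10 (the built standoff)
write_report(report, "demo.csv")
```
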