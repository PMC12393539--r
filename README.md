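# ciliovem

Quantitative 3D morphometry of ciliogenesis membrane intermediates from
isotropic volume electron microscopy (FIB-SEM) label volumes.

## What it does

Primary cilium assembly begins with membranes docking to the distal
appendages (DAs) of the mother centriole (MC) and maturing through a
series of intermediates: distal-appendage vesicles (DAV), a C-shaped
tubulovesicular membrane (CCV), a toroidal membrane (TCV), the ciliary
vesicle (CV) capping the distal end, and the cilium itself. `ciliovem`
turns a segmented FIB-SEM volume (MC body, DAs, membranes, optionally the
plasma membrane) into the measurements that distinguish these stages:

* **Centriole frame** — MC axis by principal-component fit of the body
  mask, origin at the distal face, cylindrical coordinates (r, &theta;, z).
* **Docking** — exact point-to-mesh distance from each DA tip to each
  membrane surface; a membrane is *docked* when some tip is &le; 30 nm
  away. For C-shaped membranes, tips facing the gap are excluded.
* **C-shape gap** — membrane azimuths sorted ascending; the largest
  circular difference (wrap included) is the gap:
  `gap = max_i (theta_(i+1) - theta_i)`, `coverage = 360 - gap`. A docked
  membrane with gap &lt; 180&deg; is a CCV.
* **Vesicle filter** — components must span &ge; 2 consecutive sections
  and exceed 30 nm Feret diameter.
* **Surface area** — marching-tetrahedra isosurface area (nm&sup2;), with
  hole filling so thin shells contribute a single outer surface, and
  `mean + 1 SD` enlargement flags against a reference cohort.
* **Stage classification** — one stage per MC via a fixed ladder
  (cilium &gt; CV &gt; TCV &gt; CCV &gt; DAV &gt; naked) over docked
  components.
* **Cohorts** — stage frequency tables, mean &plusmn; SEM/SD summaries,
  pooled Student t-test and one-way ANOVA.

Because the study-scale FIB-SEM volumes are not publicly deposited, the
package ships a first-class synthetic phantom generator
(`phantom_spec()`, `build_phantom()`, `sample_cohort()`) producing
voxelized MC + DA + membrane scenes with exact analytic ground truth (gap
angles, standoffs, areas, stage labels) at the study's 9 nm isotropic
resolution; the entire pipeline is validated end-to-end against it.

## Worked example

```r
library(ciliovem)

set.seed(1)
ph <- build_phantom(stage_phantom_spec("CCV", gap_deg = 93,
                                       orientation = random_rotation()))
report <- analyze_cell(ph$volume, cell_id = "demo")
report
#> <cell_report> demo: stage CCV, 1 membrane component(s), 1 docked
round(report$components[, c("gap_deg", "min_distance_nm", "surface_area_nm2")], 1)
#>   gap_deg min_distance_nm surface_area_nm2
#> 1    92.6             7.1         460364.7
```

The built phantom has a true gap of 93&deg; and an analytic membrane-tip
standoff of 10 nm; at 9 nm voxels the pipeline recovers the gap to
~0.4&deg; and the docking distance to ~3 nm (well under one voxel), and
classifies the cell as CCV.

On real data, replace the phantom with
`read_label_volume("cell.mrc")` (label roles from the JSON sidecar or
`label_map`), then `analyze_cell()`, `aggregate_cohort()` and
`compare_groups()` as above.

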